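Package: apashift
Title: Positional PolyA-Signal Enrichment and Alternative-Polyadenylation
    Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how RNA-binding proteins relate to mRNA
    polyadenylation. Computes strand-aware positional density profiles of
    consensus polyadenylation-signal hexamers (and of a second factor's
    binding-site starts) around CLIP binding-site anchors, with a circular
    permutation null; applies junction-count post-filters to splice-event
    tables; classifies proximal polyA-usage shifts (dPPAU) at fixed
    thresholds; shortlists proximity-labelling (BioID) interactors by
    peptide evidence, coverage, fold change and a Student's t-test; and
    measures fold-change concordance between paired differential tables.
    Includes seeded synthetic-data generators with known ground truth so
    the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
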