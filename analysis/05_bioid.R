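#!/usr/bin/env Rscript
# Stage 5: proximity-labelling interactor shortlist.
#
# Applies the four conjunctive evidence filters (>4 razor+unique peptides,
# >20% coverage, Student's t p < 0.05 vs the free-ligase control, log2FC
# > 1) to the simulated quantification table and compares the shortlist
# with the planted interactor set.

suppressMessages(library(apashift))

cfg <- run_config()
quant <- read.delim("results/sim/quant.tsv", stringsAsFactors = FALSE)
truth <- read.delim("results/sim/quant_truth.tsv", stringsAsFactors = FALSE)

sl <- shortlist(quant,
                min_peptides = cfg$shortlist_min_peptides,
                min_coverage = cfg$shortlist_min_coverage,
                max_p = cfg$shortlist_max_p,
                min_log2fc = cfg$shortlist_min_log2fc)
write.table(sl, "results/shortlist.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

true_ids <- truth$protein_id[truth$interactor]
hit <- sl$protein_id[sl$passes]
message("shortlisted ", length(hit), " of ", nrow(quant), " proteins; ",
        sum(hit %in% true_ids), "/", length(true_ids),
        " planted interactors recovered, ",
        sum(!hit %in% true_ids), " false positives")
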