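# apashift

Positional polyA-signal enrichment and alternative-polyadenylation shift
analysis.

RNA-binding proteins such as SR splicing factors can repress cryptic
polyadenylation by binding next to polyadenylation signals (PAS) and
blocking the 3'-end-processing machinery. Testing that idea
computationally takes a chain of analyses: where do PAS hexamers sit
relative to a factor's CLIP binding sites; where does a
3'-end-processing factor bind relative to the same anchors; do polyA-site
usage tables shift proximally or distally between conditions; which
proximity-labelling (BioID) hits are credible interactors; and do two
perturbations move gene expression concordantly. `apashift` implements
each stage as a tested R function, plus seeded synthetic-data generators
with known ground truth so the whole chain can be validated end to end
without any external data.

## What it computes

- **Positional motif profile.** For binding sites in BED6 (0-based
  half-open, strand required), windows of ±F nt (default 100) around each
  site's 5'-end anchor are extracted in RNA orientation
  (minus-strand windows reverse-complemented). The five consensus PAS
  hexamers (AATAAA, ATTAAA, AAATAA, ATAAAA, ATAAAT) are scanned exactly,
  overlaps and all; the per-offset density is total matches divided by the
  number of sites. Smoothing is a centered moving average (default 11 nt).
  Significance comes from a circular-permutation null: each window is
  rotated by an independent uniform shift, `n_perm` times, and
  `z = (obs - mean_null) / sd_null` per offset.
- **Co-binding profile.** The same positional density for a second
  factor's binding-site starts around the anchors (same contig, same
  strand, anchor's RNA orientation).
- **Splice-event filter.** Keep events with `FDR < 0.05` whose read
  support passes the type rule — A3SS/A5SS: `IJC_1 + IJC_2 + SJC >= 10`;
  RI/SE/MXE: `SJC >= 10` or IJC pair `>= 10` and `>= 5` — then tally the
  five event types.
- **dPPAU classification.** `dPPAU = mean(PPAU|condition) -
  mean(PPAU|control)` per event (percentage points); counts of
  `dPPAU > t` (proximal up) and `dPPAU < -t` (proximal down) at
  thresholds 0 and 20, strict.
- **BioID shortlist.** Razor+unique peptides `> 4`, coverage `> 20`%,
  pooled-variance Student's t `p < 0.05` on log2 LFQ intensities versus
  the free-ligase control (zeros are missing), `log2FC > 1`; all strict
  and conjunctive.
- **Fold-change concordance.** Pearson r (with p-value, r², OLS slope and
  intercept) over genes significant in both tables (or either,
  `mode = "either"`).

## Worked example

```r
library(apashift)
out <- tempfile(); dir.create(out)
res <- run_demo(out, run_config())   # simulate + run every stage
res$report
```

which prints (default master seed 17):

```
        stage                   quantity planted   recovered passed
1 pas_profile                peak_offset    20.0  21.0000000   TRUE
2 pas_profile                     peak_z      NA  24.8573542   TRUE
3      cobind                peak_offset     7.0   7.0000000   TRUE
4       dppau            proximal_up_t20   188.0 188.0000000   TRUE
5       dppau          proximal_down_t20   212.0 212.0000000   TRUE
6       bioid true_interactors_recovered    25.0  25.0000000   TRUE
7 concordance                  pearson_r     0.3   0.2948564   TRUE
```

Row by row: the smoothed PAS-density peak lands at +21 nt against a
planted mean of +20 (within the smoothing half-width), with a permutation
z of ~25 at the peak; the co-factor planted 7 nt downstream of every
anchor is recovered exactly; of 2000 polyA events with 400 planted ±30
point shifts, the `dPPAU > 20` classification recovers 188 up and 212
down — exactly the planted split; all 25 planted BioID interactors pass
the four filters with no false positives; and the fold-change correlation
estimate 0.295 recovers the planted r = 0.30.

The same stages can be run piecewise as a narrated workflow:

```sh
Rscript analysis/01_simulate.R      # writes results/sim/
Rscript analysis/02_pas_profile.R   # PAS density + permutation z
Rscript analysis/03_cobinding.R
Rscript analysis/04_splice_dppau.R
Rscript analysis/05_bioid.R
Rscript analysis/06_concordance.R
Rscript analysis/07_demo.R          # end-to-end, exits non-zero on failure
```

## Layout

- `R/` — the package: `genomic_io`, `motif_profile`, `event_tables`,
  `interactome_filter`, `concordance`, `synthetic_data`, `pipeline`.
- `analysis/` — numbered driver scripts (thin wrappers over the package).
- `tests/testthat/` — unit, property and end-to-end recovery tests.
- `vignettes/apashift-methods.Rmd` — models, conventions, parameter
  choices and limitations.
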