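#!/usr/bin/env Rscript
# Stage 6: fold-change concordance between the two simulated differential
# tables (planted Pearson r = 0.30), reported as r, r^2 and the OLS
# regression of table b on table a, using genes significant in both.

suppressMessages(library(apashift))

cfg <- run_config()
a <- read.delim("results/sim/fc_a.tsv", stringsAsFactors = FALSE)
b <- read.delim("results/sim/fc_b.tsv", stringsAsFactors = FALSE)

conc <- fc_concordance(a, b, p_thresh = cfg$concordance_p, mode = "both")
write.table(as.data.frame(conc), "results/concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "concordance over %d genes: r = %.3f (planted %.2f), r^2 = %.3f, slope = %.3f, p = %.2e",
  conc$n_genes, conc$pearson_r, cfg$r_true, conc$r_squared, conc$slope,
  conc$p_correlation))
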