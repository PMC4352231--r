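#!/usr/bin/env Rscript
# Stage 2: normalization and per-probe differential expression.
#
# Fits the 2011 and 2012 loop designs separately (median within-array
# normalization, fixed-effects population model with a common dye term) and
# merges the per-contrast tables of log2 fold change, p and BH q. Echoes
# the per-contrast significant-probe counts.

suppressPackageStartupMessages(library(anoresist))

cfg <- run_config(seed = 1, stages = c("synth", "de"))
run_pipeline(cfg, "results/run")

ct <- read_contrast_table("results/run/contrasts.tsv")
cat("Contrast table:", length(unique(ct$probe_id)), "probes x",
    length(unique(ct$contrast)), "contrasts\n")
for (co in unique(ct$contrast)) {
  sub <- ct[ct$contrast == co, ]
  cat(sprintf("  %-22s  q<0.05 & up: %4d   q<0.05 & down: %4d\n", co,
              sum(sub$q < 0.05 & sub$log2FC > 0, na.rm = TRUE),
              sum(sub$q < 0.05 & sub$log2FC < 0, na.rm = TRUE)))
}
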