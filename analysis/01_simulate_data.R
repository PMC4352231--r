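#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emulates the two array experiments (2011 triangle VKR/VKC/MAL and the 2012
# interwoven loop VKR/TEN/MAL/NG, three biological replicates per
# comparison, dye swaps), with 1000 probes carrying planted ground truth:
# cascade candidates, one violator class per filtering step, a
# down-regulated mirror class and null probes. Outputs land in results/run/.

suppressPackageStartupMessages(library(anoresist))

cfg <- run_config(seed = 1, stages = "synth")
manifest <- run_pipeline(cfg, "results/run")

truth <- read_tsv("results/run/truth.tsv")
design <- read_design("results/run/design.tsv", require_connected = FALSE)

cat("Simulated", nrow(design), "arrays over",
    length(design_populations(design)), "populations\n")
cat("Probes by planted class:\n")
print(table(truth$planted_class))
cat("Files written to results/run/:",
    paste(names(manifest$stages$synth$files), collapse = ", "), "\n")
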