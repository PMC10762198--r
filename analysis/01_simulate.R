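#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic ocean survey.
#
# Emulates the study design the pipeline targets: 6 regions (the first an
# enclosed sea with a warm deep layer) x 4 depth layers (SRF, DCM, MES,
# BAT), 12 samples per cell (288 total), 120 prokaryotic + 80 eukaryotic
# ASVs, and 65 planted association pairs (20 global, 12 regional, 8
# layer-specific, 15 environmentally driven, 10 negative). Writes the
# plain-text fixture that every later stage reads.

suppressMessages(library(pelagicnets))

seed <- 11
dataset <- generate_dataset(sim_config(seed = seed))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_fixture(dataset, "results/data")

md <- dataset$metadata
cat("samples:", nrow(md), "across",
    length(unique(md$region)), "regions x",
    length(unique(md$layer)), "layers\n")
cat("planted pairs by class:\n")
print(table(dataset$truth$class))
cat("read depth range:",
    paste(range(colSums(dataset$prok_counts$counts)), collapse = " - "),
    "(prokaryotes)\n")
cat("fixture written to results/data/\n")
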