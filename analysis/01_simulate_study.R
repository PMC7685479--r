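#!/usr/bin/env Rscript
# Step 1: generate the synthetic multi-cohort study used by the rest of the
# analysis: 3 cohorts x 150 samples over a 500-gene universe, 100 shared
# mutated genes of which 20 are planted drivers (mutation frequency 0.2,
# 30 target genes each, expression shift 1.5 noise SD); writes per-cohort
# MAF + expression TSV and the ground truth under results/sim/.

suppressPackageStartupMessages(library(driverscan))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L

cfg <- simulation_config(seed = seed)
sim <- simulate_multi_cancer(cfg)
write_simulated_study(sim, "results/sim")

for (co in sim$cohorts)
  cat(sprintf("%s: %d samples, %d mutated genes, %d mutation records\n",
              co$name, ncol(co$mutation), sum(rowSums(co$mutation) > 0),
              nrow(co$records)))
cat("planted drivers:", length(sim$truth$driver_genes),
    "| known-gene labels:", length(sim$truth$known_gene_set), "\n")
cat("written to results/sim/ (seed ", seed, ")\n", sep = "")
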