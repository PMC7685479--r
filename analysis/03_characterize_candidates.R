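#!/usr/bin/env Rscript
# Step 3: post-hoc characterization of the candidates from step 2:
# 20/20-rule classification from the simulated MAFs, oncogene/TSG rates in
# candidate vs passenger gene groups, length comparisons on a synthetic gene
# catalog, and hypergeometric over-representation of the candidate set in
# driver/known/random gene sets. Outputs under results/characterization/.

suppressPackageStartupMessages(library(driverscan))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
dir.create("results/characterization", recursive = TRUE, showWarnings = FALSE)

cands_tab <- read.delim("results/discovery/candidates.tsv")
cands <- cands_tab$gene[cands_tab$is_candidate]
universe <- sort(unique(cands_tab$gene))
truth <- readLines("results/sim/truth.tsv")
grab <- function(key) strsplit(sub(paste0("^", key, "\t"), "",
                                   truth[startsWith(truth, key)]), ",")[[1]]
drivers <- grab("drivers")
known <- read_gene_list("results/sim/known_genes.txt")
passengers <- setdiff(universe, c(cands, known))

recs <- do.call(rbind, lapply(c("C01", "C02", "C03"), function(cn)
  read_maf(file.path("results/sim", paste0(cn, ".maf")))))
cls <- classify_20_20_all(recs)
write.table(cls, "results/characterization/twenty_twenty.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
rates <- oncogene_tsg_rates(list(candidate = cands, passenger = passengers),
                            cls)
cat("20/20 classification rates by group:\n")
print(rates$rates)

# synthetic gene catalog: lengths drawn per group so the comparison machinery
# has something to contrast (this is demonstration data, not biology)
catalog <- withr::with_seed(seed, data.frame(
  gene = universe,
  known_cancer_gene = universe %in% known,
  gene_length = round(stats::rlnorm(length(universe), 9.5, 0.6) +
                        ifelse(universe %in% cands, 8000, 0)),
  protein_length = round(stats::rlnorm(length(universe), 6, 0.5))))
write.table(catalog, "results/characterization/synthetic_gene_catalog.csv",
            sep = ",", quote = FALSE, row.names = FALSE)
len <- compare_lengths(list(candidate = cands, known = intersect(known, universe),
                            other = passengers), catalog)
cat("\nlength comparisons (K-S):\n")
print(len[len$measure == "gene_length", ])
write.table(len, "results/characterization/length_comparisons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sets <- c(list(planted_drivers = drivers, known_genes = known),
          withr::with_seed(seed + 1L, setNames(
            lapply(1:5, function(i) sample(universe, 25)),
            paste0("random_set_", 1:5))))
enr <- enrich_gene_sets(cands, universe, sets)
cat("\nover-representation of the candidate set:\n")
print(enr)
write.table(enr, "results/characterization/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
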