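#!/usr/bin/env Rscript
# Step 2: run the discovery funnel on the simulated study written by step 1,
# going through the same file formats a real cohort would use: read MAF,
# filter to pathogenic classes, build the binary mutation matrix, z-score
# expression, intersect mutated genes across cohorts, SAM-test every
# pre-selected gene in every cohort (target FDR 0.2), select genes with
# significant downstream effects everywhere, and repeat on the patients free
# of known-cancer-gene alterations. Tables land in results/discovery/.

suppressPackageStartupMessages(library(driverscan))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L

cohorts <- c("C01", "C02", "C03")
datasets <- lapply(cohorts, function(cn) {
  recs <- filter_pathogenic(read_maf(file.path("results/sim", paste0(cn, ".maf"))))
  expr <- read_expression(file.path("results/sim", paste0(cn, "_expression.tsv")))
  cancer_dataset(cn, build_mutation_matrix(recs), expr)
})
known <- read_gene_list("results/sim/known_genes.txt")

res <- run_full_pipeline(datasets, known_genes = known, seed = seed,
                         sam_config = sam_config(seed = seed),
                         out_dir = "results/discovery")
print(res)

truth <- readLines("results/sim/truth.tsv")
drivers <- strsplit(sub("^drivers\t", "", truth[startsWith(truth, "drivers")]),
                    ",")[[1]]
cands <- res$candidates$gene[res$candidates$is_candidate]
cat(sprintf("driver recovery: %d/%d planted drivers among %d candidates\n",
            sum(drivers %in% cands), length(drivers), length(cands)))
if (!is.null(res$cosmic_free)) {
  cf <- res$cosmic_free$candidates
  cat(sprintf("known-gene-free re-analysis: %d/%d drivers still recovered\n",
              sum(drivers %in% cf$gene[cf$is_candidate]), length(drivers)))
}
cat("tables in results/discovery/ (gene_effects.tsv, candidates.tsv, run_report.json)\n")
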