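#' Pre-select genes mutated in every cohort
#'
#' After pathogenicity filtering, only genes carrying at least one retained
#' mutation in all cohorts are taken forward.
#'
#' @param datasets List of [cancer_dataset()] objects (>= 2).
#' @return Sorted character vector (possibly empty, with a warning).
#' @export
preselect_genes <- function(datasets) {
  stopifnot(length(datasets) >= 2L)
  per_cohort <- lapply(datasets, function(ds)
    rownames(ds$mutation)[rowSums(ds$mutation) > 0L])
  out <- sort(Reduce(intersect, per_cohort))
  if (length(out) == 0L)
    warning("no gene is mutated in every cohort: empty pre-selection")
  out
}

#' Test one mutated gene's effect on the transcriptome
#'
#' Samples are split by the gene's mutation status and SAM is run over the
#' cohort's full z-scored expression matrix; the tested gene itself is
#' removed from the significant sets before counting ("other genes").
#' Counts are also reported as proportions of the genes in the normalized
#' expression matrix.
#'
#' @param dataset A [cancer_dataset()].
#' @param gene Mutated gene symbol (must be a row of the mutation matrix).
#' @param config A [sam_config()]; its seed should already encode cohort
#'   and gene (see [run_full_pipeline()]) if order-independence is wanted.
#' @return One-row data frame: cohort, gene, testable, n_mutated_samples,
#'   n_up, n_down, prop_up, prop_down, delta_used, fdr_used.
#' @export
test_gene_effect <- function(dataset, gene, config = sam_config()) {
  gene <- normalize_symbols(gene)
  if (!gene %in% rownames(dataset$mutation))
    stop("gene ", gene, " not in mutation matrix of ", dataset$name)
  labels <- dataset$mutation[gene, ] == 1L
  res <- run_sam(dataset$expression, labels, config)
  n_total <- nrow(dataset$expression)
  if (inherits(res, "sam_untestable")) {
    return(data.frame(cohort = dataset$name, gene = gene, testable = FALSE,
                      n_mutated_samples = sum(labels),
                      n_up = NA_integer_, n_down = NA_integer_,
                      prop_up = NA_real_, prop_down = NA_real_,
                      delta_used = NA_real_, fdr_used = NA_real_,
                      stringsAsFactors = FALSE))
  }
  up <- setdiff(res$significant_up, gene)
  down <- setdiff(res$significant_down, gene)
  data.frame(cohort = dataset$name, gene = gene, testable = TRUE,
             n_mutated_samples = sum(labels),
             n_up = length(up), n_down = length(down),
             prop_up = length(up) / n_total,
             prop_down = length(down) / n_total,
             delta_used = res$delta, fdr_used = res$fdr_estimate,
             stringsAsFactors = FALSE)
}

#' Select candidate driver genes across cohorts
#'
#' A gene is a candidate driver iff it is testable in every cohort and its
#' mutation significantly affects the expression of at least `min_affected`
#' other genes (either direction) in every cohort.
#'
#' @param effects Data frame of per-gene, per-cohort rows from
#'   [test_gene_effect()].
#' @param min_affected Minimum significant other genes per cohort
#'   (default 1).
#' @param known_genes Optional known-cancer-gene symbols for annotation.
#' @return Data frame, one row per gene, sorted by total affected
#'   proportion descending: gene, is_candidate, known_cancer_gene,
#'   n_cohorts_testable, total_affected, total_prop_affected.
#' @export
select_candidates <- function(effects, min_affected = 1L, known_genes = character(0)) {
  known_genes <- normalize_symbols(known_genes)
  sp <- split(effects, effects$gene)
  rows <- lapply(sp, function(e) {
    testable_all <- all(e$testable)
    affected <- e$n_up + e$n_down
    data.frame(gene = e$gene[1L],
               is_candidate = testable_all && all(affected >= min_affected),
               known_cancer_gene = e$gene[1L] %in% known_genes,
               n_cohorts_testable = sum(e$testable),
               total_affected = if (testable_all) sum(affected) else NA_integer_,
               total_prop_affected = if (testable_all)
                 sum(e$prop_up + e$prop_down) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(out$total_prop_affected), -Inf,
                       out$total_prop_affected), out$gene)
  rownames(out) <- NULL
  out[ord, , drop = FALSE]
}

#' Restrict a cohort to patients free of known-cancer-gene alterations
#'
#' Retains exactly the samples with zero retained mutations in every known
#' gene; the expression matrix is sliced to them and re-z-scored over the
#' subset, and mutation-matrix genes with no remaining mutated sample are
#' dropped.
#'
#' @param dataset A [cancer_dataset()].
#' @param known_genes Known-cancer-gene symbols.
#' @return A new `cancer_dataset`, or a `no_eligible_samples` condition
#'   object when no sample qualifies.
#' @export
cosmic_free_subset <- function(dataset, known_genes) {
  known_genes <- normalize_symbols(known_genes)
  kg <- intersect(known_genes, rownames(dataset$mutation))
  carrier <- if (length(kg))
    colSums(dataset$mutation[kg, , drop = FALSE]) > 0L
  else rep(FALSE, ncol(dataset$mutation))
  keep <- dataset$samples[!carrier]
  if (length(keep) == 0L)
    return(no_eligible_samples_condition(paste0(
      "every sample of ", dataset$name, " carries a known-gene mutation")))
  mut <- dataset$mutation[, keep, drop = FALSE]
  mut <- mut[rowSums(mut) > 0L, , drop = FALSE]
  expr <- dataset$expression[, keep, drop = FALSE]
  attr(expr, "normalized") <- NULL        # re-standardize over the subset
  cancer_dataset(paste0(dataset$name, "_cosmicfree"), mut, expr,
                 harmonize_barcodes = FALSE)
}

# Per-(cohort, gene) SAM config with a derived seed, so per-gene runs are
# order-independent and parallelizable without changing results.
gene_sam_config <- function(config, seed, cohort, gene) {
  config$seed <- derive_seed(seed, "sam", cohort, gene)
  config
}

#' Run the full driver-discovery pipeline
#'
#' Executes the discovery funnel on a list of cohorts: pre-selection of
#' genes mutated everywhere, per-gene SAM tests in every cohort, candidate
#' selection, and (optionally) the same analysis repeated on the subsets of
#' patients free of known-cancer-gene alterations. Each per-gene SAM run
#' draws its permutations from a seed derived from (seed, cohort, gene).
#'
#' @param datasets List of [cancer_dataset()] objects.
#' @param known_genes Known-cancer-gene symbols (annotation and the
#'   COSMIC-free re-analysis).
#' @param sam_config A [sam_config()].
#' @param min_affected Candidate rule threshold (see [select_candidates()]).
#' @param seed Master seed for the per-gene permutation streams.
#' @param cosmic_free Run the known-gene-free subset re-analysis.
#' @param out_dir Optional directory: writes gene_effects.tsv,
#'   candidates.tsv, cosmic_free_candidates.tsv and run_report.json.
#' @return List of class `driver_discovery`: `preselected`, `effects`,
#'   `candidates`, `cosmic_free` (NULL or list with the same fields),
#'   `report`.
#' @export
run_full_pipeline <- function(datasets, known_genes = character(0),
                              sam_config = driverscan::sam_config(),
                              min_affected = 1L, seed = 1L,
                              cosmic_free = TRUE, out_dir = NULL) {
  known_genes <- normalize_symbols(known_genes)
  stage <- function(dsl, label) {
    pre <- preselect_genes(dsl)
    effects <- do.call(rbind, lapply(dsl, function(ds) {
      do.call(rbind, lapply(pre, function(g)
        test_gene_effect(ds, g, gene_sam_config(sam_config, seed, ds$name, g))))
    }))
    rownames(effects) <- NULL
    cands <- select_candidates(effects, min_affected, known_genes)
    list(label = label, preselected = pre, effects = effects,
         candidates = cands)
  }
  full <- stage(datasets, "full")
  cf <- NULL
  if (cosmic_free && length(known_genes)) {
    subs <- lapply(datasets, cosmic_free_subset, known_genes = known_genes)
    bad <- vapply(subs, inherits, TRUE, "no_eligible_samples")
    if (any(bad)) {
      ds_message("cosmic-free subset skipped: ",
                 paste(vapply(subs[bad], `[[`, "", "message"), collapse = "; "))
    } else {
      cf <- stage(subs, "cosmic_free")
    }
  }
  report <- assemble_report(datasets, full, cf, known_genes,
                            sam_config, min_affected, seed)
  out <- structure(list(preselected = full$preselected,
                        effects = full$effects,
                        candidates = full$candidates,
                        cosmic_free = cf, report = report),
                   class = "driver_discovery")
  if (!is.null(out_dir)) write_discovery(out, out_dir)
  out
}

write_discovery <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(x$effects, "gene_effects.tsv")
  wt(x$candidates, "candidates.tsv")
  if (!is.null(x$cosmic_free))
    wt(x$cosmic_free$candidates, "cosmic_free_candidates.tsv")
  jsonlite::write_json(x$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.driver_discovery <- function(x, ...) {
  cat("<driver_discovery>\n",
      " pre-selected genes:", length(x$preselected), "\n",
      " candidates:", sum(x$candidates$is_candidate), "\n")
  if (!is.null(x$cosmic_free))
    cat("  cosmic-free candidates:",
        sum(x$cosmic_free$candidates$is_candidate), "\n")
  invisible(x)
}
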