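#' Build a binary gene-by-sample mutation matrix
#'
#' Entry (g, s) is 1 iff at least one record maps gene g to sample s;
#' duplicate records collapse. Callers are expected to have applied
#' [filter_pathogenic()] first so the matrix reflects retained mutations
#' only.
#'
#' @param records Variant-record data frame.
#' @param samples Optional sample universe (ordered); defaults to the sorted
#'   distinct samples seen in `records`.
#' @return Integer 0/1 matrix, genes (sorted) in rows, samples in columns.
#' @export
build_mutation_matrix <- function(records, samples = NULL) {
  if (nrow(records) == 0L && is.null(samples))
    stop("no records and no sample list: cannot determine matrix dimensions")
  if (is.null(samples)) samples <- sort(unique(records$sample))
  if (anyDuplicated(samples)) stop("duplicate samples")
  genes <- sort(unique(records$gene))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- records$sample %in% samples
  if (any(!keep))
    ds_message(sum(!keep), " record(s) in samples outside the given universe ignored")
  r <- records[keep, , drop = FALSE]
  m[cbind(match(r$gene, genes), match(r$sample, samples))] <- 1L
  m
}

#' Z-score normalize an expression matrix per gene
#'
#' Each gene row is centered and scaled to unit sample standard deviation
#' (denominator n - 1). Zero-variance rows are untestable; under the default
#' policy they are dropped (and recorded in the `dropped_genes` attribute),
#' under "keep" they are set to all zeros.
#'
#' @param raw Numeric gene-by-sample matrix (>= 2 samples).
#' @param sd_policy "drop" (default) or "keep" for zero-variance rows.
#' @return The normalized matrix with attributes `normalized = TRUE` and
#'   `dropped_genes`.
#' @export
zscore_normalize <- function(raw, sd_policy = c("drop", "keep")) {
  sd_policy <- match.arg(sd_policy)
  stopifnot(is.matrix(raw), ncol(raw) >= 2L)
  mu <- rowMeans(raw)
  sds <- sqrt(rowSums((raw - mu)^2) / (ncol(raw) - 1L))
  zero <- sds == 0 | !is.finite(sds)
  if (all(zero)) stop("all gene rows have zero variance")
  dropped <- rownames(raw)[zero]
  if (sd_policy == "drop") {
    out <- (raw[!zero, , drop = FALSE] - mu[!zero]) / sds[!zero]
  } else {
    s2 <- ifelse(zero, 1, sds)
    out <- (raw - mu) / s2
    out[zero, ] <- 0
  }
  if (length(dropped))
    ds_message(length(dropped), " zero-variance gene(s) ",
               if (sd_policy == "drop") "dropped" else "set to zero")
  attr(out, "normalized") <- TRUE
  attr(out, "dropped_genes") <- dropped
  out
}

#' Assemble a cohort dataset from mutation and expression matrices
#'
#' The analysis sample set is the intersection of mutation and expression
#' barcodes; both matrices are sliced to it and the expression matrix is
#' z-scored over exactly those samples. When `harmonize_barcodes` is TRUE
#' and the two files use different barcode lengths (the TCGA convention of
#' nested barcodes), the longer barcodes are truncated to the shorter
#' length before intersecting.
#'
#' @param name Cohort label.
#' @param mutation Binary mutation matrix (genes x samples).
#' @param expression Raw or normalized expression matrix (genes x samples).
#' @param harmonize_barcodes Truncate longer barcodes to match shorter ones.
#' @param sd_policy Passed to [zscore_normalize()].
#' @return An object of class `cancer_dataset`: list with `name`, `mutation`,
#'   `expression` (z-scored), `samples`.
#' @export
cancer_dataset <- function(name, mutation, expression,
                           harmonize_barcodes = TRUE,
                           sd_policy = "drop") {
  ms <- colnames(mutation)
  es <- colnames(expression)
  if (harmonize_barcodes && length(intersect(ms, es)) == 0L) {
    lm <- unique(nchar(ms)); le <- unique(nchar(es))
    if (length(lm) == 1L && length(le) == 1L && lm != le) {
      k <- min(lm, le)
      ms2 <- substr(ms, 1L, k); es2 <- substr(es, 1L, k)
      if (!anyDuplicated(ms2) && !anyDuplicated(es2)) {
        colnames(mutation) <- ms <- ms2
        colnames(expression) <- es <- es2
        ds_message("barcodes truncated to ", k, " characters to harmonize")
      }
    }
  }
  shared <- intersect(ms, es)
  if (length(shared) == 0L)
    stop("no shared samples between mutation and expression matrices")
  n_drop <- (length(ms) - length(shared)) + (length(es) - length(shared))
  if (n_drop > 0L)
    ds_message(name, ": ", n_drop, " unmatched sample barcode(s) discarded")
  mutation <- mutation[, shared, drop = FALSE]
  expression <- expression[, shared, drop = FALSE]
  if (!isTRUE(attr(expression, "normalized")))
    expression <- zscore_normalize(expression, sd_policy = sd_policy)
  structure(list(name = name, mutation = mutation, expression = expression,
                 samples = shared),
            class = "cancer_dataset")
}

#' @export
print.cancer_dataset <- function(x, ...) {
  cat("<cancer_dataset>", x$name, "\n",
      " mutation:  ", nrow(x$mutation), "genes x", ncol(x$mutation), "samples\n",
      " expression:", nrow(x$expression), "genes x", ncol(x$expression),
      "samples (z-scored)\n")
  invisible(x)
}

#' Choose among candidate expression files via a control experiment
#'
#' When a cohort ships several expression files (microarray vs RNA-seq,
#' different normalizations), each candidate is z-scored and the SAM test is
#' run against the mutation status of well-established control genes
#' (e.g. BRCA1, BRCA2, TP53); the file whose control runs call the most
#' significant genes in total is selected (ties go to the first by input
#' order).
#'
#' @param candidates List of raw gene-by-sample matrices.
#' @param mutation Binary mutation matrix covering the control genes.
#' @param control_genes Character vector of control gene symbols.
#' @param sam_config A [sam_config()].
#' @return List with `chosen` (index into `candidates`) and `scores`
#'   (data frame: candidate, n_control_genes_tested, total_called).
#' @export
select_expression_source <- function(candidates, mutation, control_genes,
                                     sam_config = sam_config()) {
  stopifnot(length(candidates) >= 1L)
  control_genes <- normalize_symbols(control_genes)
  scores <- data.frame(candidate = seq_along(candidates),
                       n_control_genes_tested = 0L, total_called = 0L)
  for (i in seq_along(candidates)) {
    ds <- cancer_dataset(paste0("candidate", i), mutation, candidates[[i]])
    for (g in intersect(control_genes, rownames(ds$mutation))) {
      labels <- ds$mutation[g, ] == 1L
      cfg <- sam_config
      # same permutation stream per control gene across candidates, so that
      # identical candidate tables score identically and ties are real
      cfg$seed <- derive_seed(sam_config$seed, "select_source", g)
      res <- run_sam(ds$expression, labels, cfg)
      if (inherits(res, "sam_untestable")) next
      scores$n_control_genes_tested[i] <- scores$n_control_genes_tested[i] + 1L
      scores$total_called[i] <- scores$total_called[i] + res$n_called
    }
  }
  if (all(scores$n_control_genes_tested == 0L))
    stop("no control gene testable in any candidate expression file")
  chosen <- which.max(scores$total_called)  # first index wins ties
  if (sum(scores$total_called == max(scores$total_called)) > 1L)
    ds_message("tie between candidate expression files; first kept")
  list(chosen = chosen, scores = scores)
}
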