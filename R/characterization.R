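#' Classify one gene by the 20/20 rule
#'
#' Oncogene evidence: more than 20% of the gene's retained mutations are
#' missense at a recurrent locus (a protein position carrying at least two
#' of the gene's missense mutations). Tumor-suppressor evidence: more than
#' 20% are truncating. Missense records without a protein position count in
#' the denominator but cannot contribute to recurrence; when no missense
#' record has a protein position, recurrence falls back to identical
#' genomic start coordinates.
#'
#' @param records Variant records, all for one gene.
#' @param min_mutations Below this many records the gene is reported
#'   "unclassified" (default 5: smaller tallies are noise-dominated).
#' @param truncating_classes Classifications counted as truncating.
#' @return One-row data frame: gene, n_mutations,
#'   recurrent_missense_fraction, truncating_fraction, oncogene_flag,
#'   tsg_flag, combined_label (oncogene / tsg / unclassified; tsg has
#'   priority when both flags fire).
#' @export
classify_20_20 <- function(records, min_mutations = 5L,
                           truncating_classes = maf_truncating_classes()) {
  if (nrow(records) == 0L) stop("no records to classify")
  if (length(unique(records$gene)) != 1L)
    stop("records span more than one gene: ",
         paste(unique(records$gene), collapse = ", "))
  n <- nrow(records)
  mis <- records[records$classification == "Missense_Mutation", , drop = FALSE]
  locus <- mis$protein_position
  if (all(is.na(locus)) && nrow(mis) > 0L && !all(is.na(mis$start))) {
    ds_message("no protein positions for ", records$gene[1L],
               ": recurrence falls back to genomic start")
    locus <- mis$start
  }
  tab <- table(locus[!is.na(locus)])
  recurrent_positions <- names(tab)[tab >= 2L]
  n_recurrent <- sum(!is.na(locus) & as.character(locus) %in% recurrent_positions)
  rec_frac <- n_recurrent / n
  trunc_frac <- sum(records$classification %in% truncating_classes) / n
  classified <- n >= min_mutations
  onc <- classified && rec_frac > 0.20
  tsg <- classified && trunc_frac > 0.20
  label <- if (!classified) "unclassified"
           else if (tsg) "tsg" else if (onc) "oncogene" else "unclassified"
  data.frame(gene = records$gene[1L], n_mutations = n,
             recurrent_missense_fraction = rec_frac,
             truncating_fraction = trunc_frac,
             oncogene_flag = onc, tsg_flag = tsg, combined_label = label,
             stringsAsFactors = FALSE)
}

#' 20/20-classify every gene in a record table
#'
#' @param records Variant records (any number of genes).
#' @inheritParams classify_20_20
#' @return Data frame, one row per gene (see [classify_20_20()]).
#' @export
classify_20_20_all <- function(records, min_mutations = 5L,
                               truncating_classes = maf_truncating_classes()) {
  out <- do.call(rbind, lapply(split(records, records$gene), classify_20_20,
                               min_mutations = min_mutations,
                               truncating_classes = truncating_classes))
  rownames(out) <- NULL
  out
}

#' Compare gene/protein length distributions between gene groups
#'
#' Two-sample Kolmogorov-Smirnov tests (a surrogate for conservation
#' comparisons between candidate drivers, known cancer genes and the rest)
#' on gene length and protein length for every pair of groups; genes
#' without a recorded length are excluded and counted.
#'
#' @param groups Named list of gene-symbol vectors.
#' @param catalog A [read_gene_catalog()] data frame.
#' @return Data frame: group1, group2, measure, n1, n2, mean1, mean2,
#'   ks_statistic, ks_p.
#' @export
compare_lengths <- function(groups, catalog) {
  stopifnot(length(groups) >= 2L)
  pull <- function(genes, col) {
    v <- catalog[[col]][match(normalize_symbols(genes), catalog$gene)]
    v[!is.na(v)]
  }
  out <- list()
  pairs <- utils::combn(names(groups), 2L)
  for (measure in c("gene_length", "protein_length")) {
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      va <- pull(groups[[a]], measure); vb <- pull(groups[[b]], measure)
      if (length(va) < 2L || length(vb) < 2L) {
        warning("pair (", a, ", ", b, ") skipped for ", measure,
                ": fewer than 2 measurable genes")
        next
      }
      ks <- suppressWarnings(stats::ks.test(va, vb))
      out[[length(out) + 1L]] <- data.frame(
        group1 = a, group2 = b, measure = measure,
        n1 = length(va), n2 = length(vb),
        mean1 = mean(va), mean2 = mean(vb),
        ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (configurable), df = 1,
#' upper-tail p.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @param correct Apply Yates continuity correction.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square on a 2x2 table requires positive margins")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the upper-tail hypergeometric probability of seeing
#' at least the observed overlap between the query and the set inside the
#' universe (the enrichr-style test), with Benjamini-Hochberg adjustment
#' across the reported sets. Query genes outside the universe are dropped
#' with a message; sets are intersected with the universe; rows with
#' overlap below `min_overlap` are excluded before adjustment.
#'
#' @param query Gene symbols of interest.
#' @param universe All testable gene symbols.
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param min_overlap Minimum overlap to report (default 1).
#' @return Data frame sorted by p: set_name, overlap, set_size, query_size,
#'   universe_size, p_value, adjusted_p.
#' @export
enrich_gene_sets <- function(query, universe, sets, min_overlap = 1L) {
  universe <- unique(normalize_symbols(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(normalize_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    ds_message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(normalize_symbols(sets[[nm]])), universe)
    ov <- length(intersect(set, query))
    if (ov < min_overlap) return(NULL)
    p <- stats::phyper(ov - 1L, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(set),
               query_size = length(query), universe_size = length(universe),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_name = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), stringsAsFactors = FALSE))
  }
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

#' Oncogene/TSG rates per gene group, with pairwise chi-square tests
#'
#' @param groups Named list of gene-symbol vectors.
#' @param classifications Data frame from [classify_20_20_all()].
#' @return List with `rates` (per group: n, n_classified, oncogene_rate,
#'   tsg_rate, unclassified) and `tests` (pairwise 2x2 chi-square on
#'   flagged-vs-not, per flag).
#' @export
oncogene_tsg_rates <- function(groups, classifications) {
  cl <- classifications
  stat <- function(genes) {
    idx <- match(normalize_symbols(genes), cl$gene)
    idx <- idx[!is.na(idx)]
    data.frame(n = length(idx),
               n_classified = sum(cl$combined_label[idx] != "unclassified"),
               n_oncogene = sum(cl$oncogene_flag[idx]),
               n_tsg = sum(cl$tsg_flag[idx]),
               oncogene_rate = mean(cl$oncogene_flag[idx]),
               tsg_rate = mean(cl$tsg_flag[idx]))
  }
  rates <- do.call(rbind, lapply(groups, stat))
  rates <- cbind(group = names(groups), rates)
  rownames(rates) <- NULL
  tests <- list()
  if (length(groups) >= 2L) {
    pairs <- utils::combn(names(groups), 2L)
    for (flag in c("n_oncogene", "n_tsg")) {
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        ra <- rates[rates$group == a, ]; rb <- rates[rates$group == b, ]
        tab <- rbind(c(ra[[flag]], ra$n - ra[[flag]]),
                     c(rb[[flag]], rb$n - rb[[flag]]))
        res <- tryCatch(chi_square_2x2(tab), error = function(e) NULL)
        if (is.null(res)) next
        tests[[length(tests) + 1L]] <- data.frame(
          group1 = a, group2 = b,
          flag = if (flag == "n_oncogene") "oncogene" else "tsg",
          statistic = res$statistic, p_value = res$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(rates = rates, tests = do.call(rbind, tests))
}

#' Tabulate SIFT/PolyPhen verdicts already present in a MAF
#'
#' A simple functional-impact summary over the optional annotation columns;
#' records without a verdict are counted as "unannotated".
#'
#' @param records Variant records.
#' @return Data frame: tool, verdict, n.
#' @export
summarize_functional_impact <- function(records) {
  one <- function(col, tool) {
    v <- records[[col]]
    v[is.na(v) | !nzchar(v)] <- "unannotated"
    tab <- table(v)
    data.frame(tool = tool, verdict = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  rbind(one("sift", "SIFT"), one("polyphen", "PolyPhen"))
}
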