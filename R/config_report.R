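#' Validate and resolve a run configuration file
#'
#' The configuration is YAML. Recognized top-level keys: `cohorts` (list of
#' maps with `name`, `maf`, `expression` — a path or a list of candidate
#' paths), `known_genes`, `catalog`, `gene_sets` (paths), `sam` (map of
#' [sam_config()] arguments), `min_affected`, `retained_classes`,
#' `out_dir`, `seed`. Unknown keys are an error (no silent typos), missing
#' files are reported all at once, and every filled default is recorded in
#' the `defaults_filled` attribute.
#'
#' @param path Path to a YAML run configuration.
#' @return A resolved list of class `run_config`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("cohorts", "known_genes", "catalog", "gene_sets", "sam",
               "min_affected", "retained_classes", "out_dir", "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$cohorts) || length(raw$cohorts) < 1L)
    stop("config needs at least one cohort")
  sam_allowed <- c("n_permutations", "target_fdr", "s0_mode", "s0_value",
                   "min_group_size", "n_delta", "seed")
  unknown_sam <- setdiff(names(raw$sam), sam_allowed)
  if (length(unknown_sam))
    stop("unknown sam config key(s): ", paste(unknown_sam, collapse = ", "))

  defaults <- character(0)
  take <- function(value, name, default) {
    if (is.null(value)) {
      defaults <<- c(defaults, paste0(name, " = ", paste(default, collapse = ",")))
      default
    } else value
  }
  cfg <- list(
    cohorts = lapply(seq_along(raw$cohorts), function(i) {
      co <- raw$cohorts[[i]]
      bad <- setdiff(names(co), c("name", "maf", "expression"))
      if (length(bad)) stop("unknown cohort key(s): ", paste(bad, collapse = ", "))
      if (is.null(co$maf) || is.null(co$expression))
        stop("cohort ", i, " needs 'maf' and 'expression'")
      list(name = take(co$name, paste0("cohorts[", i, "]$name"),
                       paste0("cohort", i)),
           maf = co$maf, expression = unlist(co$expression))
    }),
    known_genes = raw$known_genes, catalog = raw$catalog,
    gene_sets = raw$gene_sets,
    sam = do.call(sam_config, c(raw$sam[setdiff(names(raw$sam), "seed")],
                                list(seed = take(raw$sam$seed, "sam$seed", 1L)))),
    min_affected = take(raw$min_affected, "min_affected", 1L),
    retained_classes = take(raw$retained_classes, "retained_classes",
                            maf_pathogenic_classes()),
    out_dir = raw$out_dir,
    seed = take(raw$seed, "seed", 1L))
  if (is.null(raw$sam)) defaults <- c(defaults, "sam = sam_config() defaults")

  paths <- c(unlist(lapply(cfg$cohorts, function(co) c(co$maf, co$expression))),
             cfg$known_genes, cfg$catalog, cfg$gene_sets)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  attr(cfg, "defaults_filled") <- defaults
  structure(cfg, class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' @param config A `run_config` (or compatible list).
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$sam <- unclass(out$sam)
  out$sam$s0_value <- if (is.na(out$sam$s0_value)) NULL else out$sam$s0_value
  attr(out, "defaults_filled") <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the discovery pipeline from a validated configuration
#'
#' Reads each cohort's MAF (choosing among multiple expression candidates
#' with [select_expression_source()] when more than one is given), applies
#' the pathogenicity filter, builds the matrices and runs
#' [run_full_pipeline()].
#'
#' @param config A [validate_config()] result.
#' @return A `driver_discovery` object.
#' @export
run_from_config <- function(config) {
  known <- if (!is.null(config$known_genes))
    read_gene_list(config$known_genes) else character(0)
  datasets <- lapply(config$cohorts, function(co) {
    recs <- filter_pathogenic(read_maf(co$maf), config$retained_classes)
    mut <- build_mutation_matrix(recs)
    exprs <- lapply(co$expression, read_expression)
    if (length(exprs) > 1L) {
      controls <- if (length(known)) known else rownames(mut)[1:3]
      pick <- select_expression_source(exprs, mut, controls, config$sam)
      ds_message(co$name, ": expression candidate ", pick$chosen, " selected")
      exprs <- exprs[pick$chosen]
    }
    cancer_dataset(co$name, mut, exprs[[1L]])
  })
  run_full_pipeline(datasets, known_genes = known, sam_config = config$sam,
                    min_affected = config$min_affected, seed = config$seed,
                    out_dir = config$out_dir)
}

#' Assemble the structured run report
#'
#' Machine-readable funnel summary: per-cohort input sizes, the
#' pre-selection intersection, testable genes, candidates, the
#' known-gene-free re-analysis, and the exact configuration and seed.
#'
#' @param datasets Input cohort datasets.
#' @param full Full-cohort stage results (internal structure of
#'   [run_full_pipeline()]).
#' @param cf COSMIC-free stage results or NULL.
#' @param known_genes,sam_config,min_affected,seed Run parameters echoed
#'   into the report.
#' @return A nested list (serializable to JSON).
#' @export
assemble_report <- function(datasets, full, cf, known_genes,
                            sam_config, min_affected, seed) {
  cohort_counts <- lapply(datasets, function(ds) {
    list(name = ds$name,
         n_samples = length(ds$samples),
         n_genes_expression = nrow(ds$expression),
         n_genes_mutated = sum(rowSums(ds$mutation) > 0L))
  })
  stage_summary <- function(st) {
    if (is.null(st)) return(NULL)
    testable <- stats::aggregate(testable ~ gene, st$effects, all)
    list(n_preselected = length(st$preselected),
         n_testable_all_cohorts = sum(testable$testable),
         n_candidates = sum(st$candidates$is_candidate),
         n_candidates_known = sum(st$candidates$is_candidate &
                                    st$candidates$known_cancer_gene),
         candidates = st$candidates$gene[st$candidates$is_candidate])
  }
  list(schema_version = "1.0",
       seed = seed,
       sam = unclass(sam_config),
       min_affected = min_affected,
       n_known_genes = length(known_genes),
       cohorts = unname(cohort_counts),
       full = stage_summary(full),
       cosmic_free = stage_summary(cf))
}
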