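#' Simulation configuration for synthetic multi-cohort datasets
#'
#' Defines the statistical structure the generator emulates: several
#' cohorts sharing a pool of mutated genes, a subset of which are planted
#' drivers whose mutations shift the expression of target genes; all other
#' mutated genes are passengers with no expression effect.
#'
#' @param n_cohorts Number of cohorts (>= 1; the multi-cancer generator
#'   requires >= 2).
#' @param n_samples Samples per cohort.
#' @param n_genes Size of the expression gene universe.
#' @param n_shared_mutated_genes Genes mutated in every cohort (drivers +
#'   shared passengers).
#' @param n_planted_drivers Number of driver genes (<= shared pool).
#' @param driver_mutation_frequency Per-sample mutation probability for
#'   driver genes, in (0, 1).
#' @param passenger_mutation_frequency Per-sample mutation probability for
#'   pool passenger genes, in [0, 1).
#' @param targets_per_driver Number of genes whose expression each driver
#'   perturbs.
#' @param effect_size_delta Expression shift in mutated samples, in units
#'   of the noise SD.
#' @param noise_sd Gaussian noise SD around each gene's baseline mean.
#' @param known_gene_fraction Fraction of non-driver genes labeled "known
#'   cancer gene" (COSMIC-style annotation for stratified analyses).
#' @param variant_class_mix Named probabilities over MAF
#'   Variant_Classification values, summing to 1; defaults to a
#'   non-synonymous mix so that the pathogenicity filter is a no-op on
#'   simulated records.
#' @param hotspot_concentration Fraction of a gene's missense records
#'   placed at one shared protein position.
#' @param min_mutated_per_driver Generation fails fast unless
#'   driver_mutation_frequency * n_samples reaches this (the SAM
#'   minimum group size).
#' @param seed Integer master seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 3L, n_samples = 150L,
                              n_genes = 500L, n_shared_mutated_genes = 100L,
                              n_planted_drivers = 20L,
                              driver_mutation_frequency = 0.2,
                              passenger_mutation_frequency = 0.05,
                              targets_per_driver = 30L,
                              effect_size_delta = 1.5, noise_sd = 1,
                              known_gene_fraction = 0.1,
                              variant_class_mix = default_variant_class_mix(),
                              hotspot_concentration = 0.3,
                              min_mutated_per_driver = 3L, seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_shared_mutated_genes = as.integer(n_shared_mutated_genes),
              n_planted_drivers = as.integer(n_planted_drivers),
              driver_mutation_frequency = driver_mutation_frequency,
              passenger_mutation_frequency = passenger_mutation_frequency,
              targets_per_driver = as.integer(targets_per_driver),
              effect_size_delta = effect_size_delta, noise_sd = noise_sd,
              known_gene_fraction = known_gene_fraction,
              variant_class_mix = variant_class_mix,
              hotspot_concentration = hotspot_concentration,
              min_mutated_per_driver = as.integer(min_mutated_per_driver),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_variant_class_mix <- function() {
  c(Missense_Mutation = 0.70, Nonsense_Mutation = 0.10,
    Frame_Shift_Del = 0.05, Frame_Shift_Ins = 0.05,
    Splice_Site = 0.05, In_Frame_Del = 0.025, In_Frame_Ins = 0.025)
}

validate_simulation_config <- function(cfg) {
  fr <- c(cfg$driver_mutation_frequency, cfg$passenger_mutation_frequency,
          cfg$known_gene_fraction, cfg$hotspot_concentration)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$driver_mutation_frequency <= 0 || cfg$driver_mutation_frequency >= 1)
    stop("driver_mutation_frequency must lie in (0, 1)")
  if (abs(sum(cfg$variant_class_mix) - 1) > 1e-12)
    stop("variant_class_mix probabilities must sum to 1")
  if (is.null(names(cfg$variant_class_mix)))
    stop("variant_class_mix must be named by classification")
  if (!(cfg$n_planted_drivers <= cfg$n_shared_mutated_genes &&
        cfg$n_shared_mutated_genes <= cfg$n_genes))
    stop("need n_planted_drivers <= n_shared_mutated_genes <= n_genes")
  if (cfg$driver_mutation_frequency * cfg$n_samples < cfg$min_mutated_per_driver)
    stop("driver_mutation_frequency * n_samples = ",
         cfg$driver_mutation_frequency * cfg$n_samples,
         " is below the minimum mutated-group size of ",
         cfg$min_mutated_per_driver)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  invisible(cfg)
}

#' Draw the shared ground truth for a multi-cohort simulation
#'
#' Fixes, from the master seed: gene names, the shared mutated pool, which
#' pool genes are drivers, each driver's target genes and per-target effect
#' sign, baseline expression means, the known-cancer-gene subset, and the
#' per-cohort mutated-sample set of every pool gene. Drivers are drawn
#' outside the known-gene subset (planted drivers emulate novel genes).
#'
#' @param config A [simulation_config()].
#' @return List of class `planted_truth` with elements `genes`,
#'   `mutated_pool`, `driver_genes`, `passenger_genes`, `target_map`,
#'   `effect_sign`, `baseline_mean`, `known_gene_set`, `mutated_samples`
#'   (cohort -> gene -> sample vector), `samples` (cohort -> barcodes).
#' @export
draw_planted_truth <- function(config) {
  validate_simulation_config(config)
  withr::with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    pool <- sort(sample(genes, config$n_shared_mutated_genes))
    drivers <- sort(sample(pool, config$n_planted_drivers))
    passengers <- setdiff(pool, drivers)
    target_map <- list()
    effect_sign <- list()
    for (d in drivers) {
      targets <- sample(setdiff(genes, d), config$targets_per_driver)
      target_map[[d]] <- sort(targets)
      sg <- sample(c(-1, 1), config$targets_per_driver, replace = TRUE)
      names(sg) <- targets
      effect_sign[[d]] <- sg[sort(targets)]
    }
    baseline <- stats::rnorm(config$n_genes)
    names(baseline) <- genes
    n_known <- round(config$known_gene_fraction * config$n_genes)
    known <- sort(sample(setdiff(genes, drivers),
                         min(n_known, config$n_genes - length(drivers))))
    samples <- list()
    mutated <- list()
    for (k in seq_len(config$n_cohorts)) {
      cname <- sprintf("C%02d", k)
      sn <- sprintf("%s-S%04d", cname, seq_len(config$n_samples))
      samples[[cname]] <- sn
      ms <- list()
      for (g in pool) {
        p <- if (g %in% drivers) config$driver_mutation_frequency
             else config$passenger_mutation_frequency
        hit <- stats::runif(config$n_samples) < p
        if (!any(hit)) hit[sample.int(config$n_samples, 1L)] <- TRUE
        ms[[g]] <- sn[hit]
      }
      mutated[[cname]] <- ms
    }
  })
  structure(list(genes = genes, mutated_pool = pool, driver_genes = drivers,
                 passenger_genes = passengers, target_map = target_map,
                 effect_sign = effect_sign, baseline_mean = baseline,
                 known_gene_set = known, mutated_samples = mutated,
                 samples = samples, config_seed = config$seed),
            class = "planted_truth")
}

#' Simulate one cohort under a drawn truth
#'
#' Expression of gene t in sample s is baseline_t + Gaussian noise; when s
#' is mutated in driver d and t is one of d's targets, the recorded signed
#' shift effect_size_delta * noise_sd is added. The mutation matrix is the
#' indicator of the emitted variant records (one record per (gene, sample)
#' mutation event).
#'
#' @param config A [simulation_config()].
#' @param cohort_index Cohort number (1-based).
#' @param truth A [draw_planted_truth()] result for the same config/seed.
#' @return List with `name`, `mutation` (binary matrix), `expression`
#'   (raw gene-by-sample matrix) and `records` (variant-record data frame).
#' @export
simulate_cohort <- function(config, cohort_index, truth) {
  validate_simulation_config(config)
  if (!inherits(truth, "planted_truth") || truth$config_seed != config$seed)
    stop("truth was drawn for seed ", truth$config_seed,
         " but config has seed ", config$seed)
  cname <- sprintf("C%02d", cohort_index)
  if (!cname %in% names(truth$samples))
    stop("truth has no cohort ", cname, " (n_cohorts mismatch)")
  sn <- truth$samples[[cname]]
  ms <- truth$mutated_samples[[cname]]
  withr::with_seed(derive_seed(config$seed, "cohort", cohort_index), {
    expr <- matrix(stats::rnorm(config$n_genes * config$n_samples,
                                sd = config$noise_sd),
                   config$n_genes, config$n_samples,
                   dimnames = list(truth$genes, sn))
    expr <- expr + truth$baseline_mean
    for (d in truth$driver_genes) {
      mut <- ms[[d]]
      shift <- truth$effect_sign[[d]] * config$effect_size_delta * config$noise_sd
      expr[names(shift), mut] <- expr[names(shift), mut] + shift
    }
    recs <- simulate_records(config, ms, truth$genes)
  })
  mutation <- build_mutation_matrix(recs, samples = sn)
  list(name = cname, mutation = mutation, expression = expr, records = recs)
}

# One variant record per (gene, sample) event; classification from the
# configured mix; missense records get a protein position, concentrated at
# a per-gene hotspot with the configured probability.
simulate_records <- function(config, mutated_samples, genes) {
  gene <- rep(names(mutated_samples), lengths(mutated_samples))
  sample <- unlist(mutated_samples, use.names = FALSE)
  n <- length(gene)
  if (n == 0L) return(empty_variant_records())
  cls <- sample(names(config$variant_class_mix), n, replace = TRUE,
                prob = config$variant_class_mix)
  hotspot <- sample.int(1000L, length(genes))
  names(hotspot) <- genes
  pos <- rep(NA_integer_, n)
  mis <- which(cls == "Missense_Mutation")
  if (length(mis)) {
    at_hot <- stats::runif(length(mis)) < config$hotspot_concentration
    pos[mis] <- ifelse(at_hot, hotspot[gene[mis]],
                       sample.int(1000L, length(mis), replace = TRUE))
  }
  variant_records(gene, sample, cls, protein_position = pos)
}

#' Simulate a full multi-cohort study with planted drivers
#'
#' Cohorts share driver genes and the shared mutated-gene pool (fixed by
#' one truth draw) but have independent samples, expression noise and
#' variant records.
#'
#' @param config A [simulation_config()] with n_cohorts >= 2.
#' @return List with `cohorts` (list of [simulate_cohort()] results) and
#'   `truth` (the shared [draw_planted_truth()]).
#' @export
simulate_multi_cancer <- function(config) {
  stopifnot(config$n_cohorts >= 2L)
  truth <- draw_planted_truth(config)
  cohorts <- lapply(seq_len(config$n_cohorts),
                    function(k) simulate_cohort(config, k, truth))
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  list(cohorts = cohorts, truth = truth)
}

#' Simulate a single-gene MAF for the 20/20 classifier
#'
#' Emits exactly `n_mutations` records for one gene:
#' round(n * missense_fraction) missense (round-half-even), of which
#' round(hotspot_concentration * n_missense) share one protein position;
#' round(n * truncating_fraction) truncating (nonsense/frameshift/splice);
#' the remainder other non-silent classes.
#'
#' @param n_mutations Total records.
#' @param missense_fraction,truncating_fraction Fractions with
#'   missense_fraction + truncating_fraction <= 1.
#' @param hotspot_concentration Fraction of missense at the shared position.
#' @param seed Integer seed.
#' @param gene Gene symbol for the records.
#' @return Variant-record data frame.
#' @export
simulate_maf_for_2020 <- function(n_mutations, missense_fraction,
                                  truncating_fraction,
                                  hotspot_concentration = 0, seed = 1L,
                                  gene = "GENE1") {
  stopifnot(missense_fraction >= 0, truncating_fraction >= 0,
            missense_fraction + truncating_fraction <= 1)
  n_mis <- round(n_mutations * missense_fraction)
  n_trunc <- round(n_mutations * truncating_fraction)
  if (n_mis + n_trunc > n_mutations)
    stop("rounding makes missense + truncating exceed n_mutations")
  n_hot <- round(hotspot_concentration * n_mis)
  n_other <- n_mutations - n_mis - n_trunc
  withr::with_seed(seed, {
    hotspot_pos <- sample.int(900L, 1L)
    mis_pos <- c(rep(hotspot_pos, n_hot),
                 if (n_mis > n_hot) 900L + sample.int(5000L, n_mis - n_hot))
    trunc_cls <- sample(c("Nonsense_Mutation", "Frame_Shift_Del",
                          "Frame_Shift_Ins", "Splice_Site"),
                        n_trunc, replace = TRUE)
    other_cls <- sample(c("In_Frame_Del", "In_Frame_Ins"),
                        n_other, replace = TRUE)
  })
  cls <- c(rep("Missense_Mutation", n_mis), trunc_cls, other_cls)
  pos <- c(mis_pos, rep(NA_integer_, n_trunc + n_other))
  variant_records(gene = rep(gene, n_mutations),
                  sample = sprintf("S%04d", seq_len(n_mutations)),
                  classification = cls, protein_position = pos)
}

#' Write a simulated study to disk
#'
#' Emits per cohort a MAF and an expression TSV, plus a plain-text truth
#' file (key-value lines: drivers, per-driver targets and signs, known
#' genes) so that downstream runs can be checked against the plant.
#'
#' @param sim A [simulate_multi_cancer()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (co in sim$cohorts) {
    write_maf(co$records, file.path(dir, paste0(co$name, ".maf")))
    write_expression(co$expression,
                     file.path(dir, paste0(co$name, "_expression.tsv")))
  }
  tr <- sim$truth
  lines <- c(paste0("drivers\t", paste(tr$driver_genes, collapse = ",")),
             paste0("known_genes\t", paste(tr$known_gene_set, collapse = ",")),
             vapply(tr$driver_genes, function(d) {
               paste0("targets\t", d, "\t",
                      paste(names(tr$effect_sign[[d]]), collapse = ","), "\t",
                      paste(tr$effect_sign[[d]], collapse = ","))
             }, ""))
  writeLines(lines, file.path(dir, "truth.tsv"))
  writeLines(tr$known_gene_set, file.path(dir, "known_genes.txt"))
  invisible(dir)
}
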