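# Shared fixture builders; everything is generated in code at test time.

# Standardized random expression matrix with named dims.
rand_expr <- function(n_genes, n_samples, seed, zscore = TRUE) {
  m <- withr::with_seed(seed, matrix(stats::rnorm(n_genes * n_samples),
                                     n_genes, n_samples))
  dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_samples)))
  if (zscore) m <- suppressMessages(zscore_normalize(m))
  m
}

# A small multi-cohort simulation config that keeps tests fast.
small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_cohorts = 3L, n_samples = 60L, n_genes = 120L,
               n_shared_mutated_genes = 20L, n_planted_drivers = 5L,
               driver_mutation_frequency = 0.25,
               passenger_mutation_frequency = 0.05,
               targets_per_driver = 12L, effect_size_delta = 2,
               known_gene_fraction = 0.15, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

toy_maf_lines <- function() {
  c("#version 2.4",
    "# comment line",
    paste("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
          "Protein_Change", sep = "\t"),
    paste("TP53", "S1", "Missense_Mutation", "p.R175H", sep = "\t"),
    paste("brca1 ", "S2", "Nonsense_Mutation", "p.Q12*", sep = "\t"),
    paste("KRAS", "S1", "Silent", "", sep = "\t"))
}

write_toy_maf <- function(path = withr::local_tempfile(fileext = ".maf",
                                                       .local_envir = parent.frame())) {
  writeLines(toy_maf_lines(), path)
  path
}

# Independent pooled-variance two-sample t oracle for one gene row.
pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Independent O(n^2) scan for SAM cutpoints, written against the stated
# rule rather than the implementation.
brute_force_cutpoints <- function(d, dbar, delta) {
  ds <- sort(d)
  up <- Inf
  for (k in seq_along(ds)) {
    if (ds[k] > 0 && (ds[k] - dbar[k]) > delta) { up <- ds[k]; break }
  }
  low <- -Inf
  for (k in rev(seq_along(ds))) {
    if (ds[k] < 0 && (dbar[k] - ds[k]) > delta) { low <- ds[k]; break }
  }
  list(cut_up = up, cut_low = low,
       up = sort(names(d)[d >= up]), down = sort(names(d)[d <= low]))
}

# Build a cancer_dataset from a simulated cohort.
as_dataset <- function(cohort) {
  suppressMessages(cancer_dataset(cohort$name, cohort$mutation,
                                  cohort$expression))
}
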