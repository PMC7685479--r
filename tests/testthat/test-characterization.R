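test_that("20/20 classification follows its defining fractions", {
  # 5 missense at one position + 5 in-frame others: recurrent fraction 0.5
  r <- variant_records(gene = "G1", sample = paste0("s", 1:10),
                       classification = c(rep("Missense_Mutation", 5),
                                          rep("In_Frame_Del", 5)),
                       protein_position = c(rep(175L, 5), rep(NA, 5)))
  res <- classify_20_20(r)
  expect_equal(res$recurrent_missense_fraction, 0.5)
  expect_true(res$oncogene_flag)
  expect_equal(res$combined_label, "oncogene")

  # 3 nonsense + 7 missense at distinct positions: TSG only
  r2 <- variant_records(gene = "G2", sample = paste0("s", 1:10),
                        classification = c(rep("Nonsense_Mutation", 3),
                                           rep("Missense_Mutation", 7)),
                        protein_position = c(rep(NA, 3), 1:7))
  res2 <- classify_20_20(r2)
  expect_equal(res2$truncating_fraction, 0.3)
  expect_true(res2$tsg_flag)
  expect_false(res2$oncogene_flag)
  expect_equal(res2$combined_label, "tsg")

  expect_error(classify_20_20(r[0, ]), "no records")
  expect_error(classify_20_20(rbind(r, r2)), "more than one gene")
})

test_that("flags flip exactly at the strict 20% boundary", {
  for (frac in c(0.19, 0.20, 0.21)) {
    n <- 100L
    rec <- simulate_maf_for_2020(n, missense_fraction = frac,
                                 truncating_fraction = frac,
                                 hotspot_concentration = 1, seed = 7)
    res <- classify_20_20(rec)
    expect_equal(res$recurrent_missense_fraction, frac)
    expect_equal(res$truncating_fraction, frac)
    expect_equal(res$oncogene_flag, frac > 0.20)
    expect_equal(res$tsg_flag, frac > 0.20)
  }
})

test_that("fractions match a brute-force position-histogram recount", {
  rec <- withr::with_seed(17, {
    n <- 200L
    cls <- sample(c("Missense_Mutation", "Nonsense_Mutation", "In_Frame_Del",
                    "Frame_Shift_Del"), n, replace = TRUE)
    pos <- ifelse(cls == "Missense_Mutation",
                  sample.int(40, n, replace = TRUE), NA)
    variant_records(gene = "G1", sample = paste0("s", 1:n),
                    classification = cls, protein_position = pos)
  })
  res <- classify_20_20(rec)
  hist <- table(rec$protein_position[rec$classification == "Missense_Mutation"])
  n_rec <- 0L; n_trunc <- 0L
  for (i in seq_len(nrow(rec))) {
    cl <- rec$classification[i]
    if (cl == "Missense_Mutation" &&
        hist[as.character(rec$protein_position[i])] >= 2) n_rec <- n_rec + 1L
    if (cl %in% c("Nonsense_Mutation", "Frame_Shift_Del")) n_trunc <- n_trunc + 1L
  }
  expect_equal(res$recurrent_missense_fraction, n_rec / nrow(rec))
  expect_equal(res$truncating_fraction, n_trunc / nrow(rec))
})

test_that("classification is order-invariant; fractions survive uniform duplication", {
  rec <- simulate_maf_for_2020(40, 0.5, 0.3, hotspot_concentration = 1, seed = 3)
  shuffled <- rec[withr::with_seed(4, sample(nrow(rec))), ]
  expect_equal(classify_20_20(shuffled), classify_20_20(rec))
  doubled <- rbind(rec, rec)
  res1 <- classify_20_20(rec); res2 <- classify_20_20(doubled)
  expect_equal(res2$n_mutations, 2L * res1$n_mutations)
  expect_equal(res2$recurrent_missense_fraction, res1$recurrent_missense_fraction)
  expect_equal(res2$truncating_fraction, res1$truncating_fraction)
})

test_that("sparse genes are reported unclassified rather than silently false", {
  rec <- simulate_maf_for_2020(4, 1, 0, hotspot_concentration = 1, seed = 5)
  res <- classify_20_20(rec, min_mutations = 5)
  expect_equal(res$combined_label, "unclassified")
  expect_false(res$oncogene_flag)
})

test_that("length comparisons reduce to K-S facts on constructed groups", {
  catalog <- data.frame(gene = paste0("G", 1:200),
                        known_cancer_gene = FALSE,
                        gene_length = c(1:100, 1001:1100),
                        protein_length = c(1:100, 1001:1100) / 3)
  same <- compare_lengths(list(a = paste0("G", 1:50), b = paste0("G", 1:50)),
                          catalog)
  expect_true(all(same$ks_statistic == 0))
  expect_true(all(same$ks_p == 1))
  disjoint <- compare_lengths(list(short = paste0("G", 1:100),
                                   long = paste0("G", 101:200)), catalog)
  expect_true(all(disjoint$ks_statistic == 1))
})

test_that("K-S statistic matches an O(n^2) empirical-CDF scan", {
  withr::with_seed(23, {
    la <- sample.int(5000, 50); lb <- sample.int(5000, 50)
  })
  catalog <- data.frame(gene = paste0("G", 1:100), known_cancer_gene = FALSE,
                        gene_length = c(la, lb),
                        protein_length = NA_real_)
  res <- suppressWarnings(            # protein lengths absent: pair skipped
    compare_lengths(list(a = paste0("G", 1:50), b = paste0("G", 51:100)),
                    catalog))
  d_oracle <- 0
  for (x in c(la, lb)) {                     # brute-force sup over ECDF gaps
    fa <- sum(la <= x) / length(la)
    fb <- sum(lb <= x) / length(lb)
    d_oracle <- max(d_oracle, abs(fa - fb))
  }
  expect_equal(res$ks_statistic[res$measure == "gene_length"], d_oracle)
})

test_that("2x2 chi-square follows the Pearson formula", {
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  diag <- chi_square_2x2(rbind(c(20, 0), c(0, 20)))
  expect_equal(diag$statistic, 40)           # chi^2 = n for a perfect diagonal
  tab <- rbind(c(12, 33), c(7, 41))
  res <- chi_square_2x2(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)   # independent evaluation
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(res$statistic, 1, lower.tail = FALSE))
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "margins")
})

test_that("over-representation p-values follow the hypergeometric tail", {
  universe <- paste0("G", 1:100)
  sets <- list(S = paste0("G", 1:10))
  query <- c(paste0("G", 1:5), paste0("G", 50:64))   # overlap 5, query 20
  res <- enrich_gene_sets(query, universe, sets)
  p_oracle <- sum(stats::dhyper(5:10, 10, 90, 20))   # direct pmf summation
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  full <- enrich_gene_sets(universe, universe, list(S = universe))
  expect_equal(full$p_value, 1)
  expect_equal(full$overlap, 100L)

  none <- enrich_gene_sets(paste0("G", 1:5), universe,
                           list(S = paste0("G", 90:99)), min_overlap = 1)
  expect_equal(nrow(none), 0L)
})

test_that("hypergeometric p equals one-sided Fisher exact; BH is monotone", {
  withr::with_seed(41, {
    for (i in 1:25) {
      N <- sample(30:200, 1)
      K <- sample(5:20, 1)
      nq <- sample(5:25, 1)
      universe <- paste0("G", 1:N)
      set <- sample(universe, K)
      query <- sample(universe, nq)
      res <- enrich_gene_sets(query, universe, list(S = set), min_overlap = 0)
      ov <- length(intersect(set, query))
      tab <- rbind(c(ov, nq - ov), c(K - ov, N - K - (nq - ov)))
      p_fisher <- stats::fisher.test(tab, alternative = "greater")$p.value
      expect_equal(res$p_value, p_fisher, tolerance = 1e-9)
    }
  })
  sets <- withr::with_seed(42, lapply(1:15, function(i)
    sample(paste0("G", 1:100), sample(5:30, 1))))
  names(sets) <- paste0("S", 1:15)
  res <- enrich_gene_sets(paste0("G", 1:20), paste0("G", 1:100), sets)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  expect_true(all(diff(res$adjusted_p[order(res$p_value)]) >= -1e-15))
})

test_that("group oncogene/TSG rates and contrasts behave on constructed MAFs", {
  mk <- function(gene, hotspot) simulate_maf_for_2020(
    30, missense_fraction = 0.8, truncating_fraction = 0.1,
    hotspot_concentration = hotspot, seed = hash31(gene) %% 1000L, gene = gene)
  driverish <- paste0("DRV", 1:8)
  passengerish <- paste0("PSG", 1:8)
  recs <- do.call(rbind, c(lapply(driverish, mk, hotspot = 0.9),
                           lapply(passengerish, mk, hotspot = 0)))
  cl <- classify_20_20_all(recs)
  rates <- oncogene_tsg_rates(list(driver_like = driverish,
                                   passenger_like = passengerish), cl)
  r_drv <- rates$rates$oncogene_rate[rates$rates$group == "driver_like"]
  r_psg <- rates$rates$oncogene_rate[rates$rates$group == "passenger_like"]
  expect_gt(r_drv, r_psg)
  expect_equal(r_drv, mean(vapply(driverish, function(g)
    classify_20_20(recs[recs$gene == g, ])$oncogene_flag, TRUE)))
  # identical groups give a null chi-square
  both <- oncogene_tsg_rates(list(a = driverish, b = driverish), cl)
  expect_true(all(both$tests$p_value == 1))
  ten <- data.frame(gene = paste0("X", 1:10),
                    oncogene_flag = rep(c(TRUE, FALSE), c(4, 6)),
                    tsg_flag = FALSE,
                    combined_label = rep(c("oncogene", "unclassified"), c(4, 6)))
  r <- oncogene_tsg_rates(list(g = ten$gene), ten)
  expect_equal(r$rates$oncogene_rate, 0.4)
})

test_that("functional-impact tabulation counts SIFT/PolyPhen verdicts", {
  rec <- variant_records(gene = "G1", sample = paste0("s", 1:4),
                         classification = "Missense_Mutation",
                         sift = c("deleterious", "tolerated", NA, "deleterious"),
                         polyphen = c("probably_damaging", NA, NA, "benign"))
  tab <- summarize_functional_impact(rec)
  expect_equal(tab$n[tab$tool == "SIFT" & tab$verdict == "deleterious"], 2L)
  expect_equal(tab$n[tab$tool == "PolyPhen" & tab$verdict == "unannotated"], 2L)
})
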