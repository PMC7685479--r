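test_that("d-statistic matches the stated formula and the pooled-t oracle", {
  expr <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                 dimnames = list("g1", paste0("s", 1:6)))
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  st <- sam_compute_stats(expr, labels, s0 = 0)
  expect_equal(unname(st$r), 3)
  expect_equal(unname(st$s), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(st$d), 3 / sqrt(2 / 3), tolerance = 1e-12)
  tt <- stats::t.test(expr[1, labels], expr[1, !labels], var.equal = TRUE)
  expect_equal(unname(st$d), unname(tt$statistic), tolerance = 1e-12)
})

test_that("d is 0 for equal class means and shrinks monotonically in s0", {
  expr <- matrix(c(1, 3, 2, 1, 3, 2), 1, 6,
                 dimnames = list("g1", paste0("s", 1:6)))
  labels <- rep(c(FALSE, TRUE), each = 3)
  expect_equal(unname(sam_compute_stats(expr, labels, 0)$d), 0)
  expr2 <- rand_expr(20, 12, seed = 3)
  labels2 <- rep(c(TRUE, FALSE), each = 6)
  dmag <- sapply(c(0, 0.5, 2, 10, 100),
                 function(s0) max(abs(sam_compute_stats(expr2, labels2, s0)$d)))
  expect_true(all(diff(dmag) < 0))
})

test_that("with s0 = 0 the d ranking equals the pooled-t ranking", {
  for (seed in 1:5) {
    expr <- rand_expr(40, 16, seed = seed)
    labels <- withr::with_seed(seed + 100, sample(rep(c(TRUE, FALSE), each = 8)))
    d <- sam_compute_stats(expr, labels, 0)$d
    t_oracle <- apply(expr, 1, function(x)
      pooled_t_oracle(x[!labels], x[labels]))
    expect_equal(order(d), order(t_oracle))
    expect_equal(unname(d), unname(t_oracle), tolerance = 1e-10)
  }
})

test_that("s0 estimation: degenerate tie, fallback, and CV improvement", {
  # all scatters equal: every candidate ties, smallest percentile wins
  r <- withr::with_seed(1, stats::rnorm(50))
  s <- rep(0.7, 50)
  expect_equal(sam_estimate_s0(r, s), 0.7)
  # < 20 genes falls back to median(s)
  s_small <- withr::with_seed(2, stats::runif(10, 0.5, 2))
  expect_message(s0 <- sam_estimate_s0(stats::rnorm(10), s_small), "median")
  expect_equal(s0, stats::median(s_small))
  # heavy mean-variance dependence: chosen s0 > 0 and CV no worse than at 0
  withr::with_seed(3, {
    s <- stats::runif(500, 0.05, 0.2)
    r <- stats::rnorm(500, sd = s + 0.01)   # d at s0=0 explodes for tiny s
  })
  s0 <- sam_estimate_s0(r, s)
  expect_gt(s0, 0)
  cv_of <- function(s0) {
    ord <- order(s)
    win <- floor((seq_along(s) - 1) * 100 / length(s)) + 1
    mads <- vapply(split((r / (s + s0))[ord], win), stats::mad, 0)
    stats::sd(mads) / mean(mads)
  }
  expect_lte(cv_of(s0), cv_of(0))
})

test_that("permutations enumerate exactly when feasible, else draw distinct seeded", {
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  P <- sam_permute(labels, 100, seed = 1)
  expect_equal(ncol(P), choose(5, 2))
  expect_true(isTRUE(attr(P, "exact")))
  keys <- apply(P, 2, paste, collapse = "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(colSums(P) == 2))

  labels2 <- rep(c(TRUE, FALSE), c(10, 20))
  P1 <- sam_permute(labels2, 100, seed = 5)
  P2 <- sam_permute(labels2, 100, seed = 5)
  P3 <- sam_permute(labels2, 100, seed = 6)
  expect_equal(ncol(P1), 100L)
  expect_equal(anyDuplicated(apply(P1, 2, paste, collapse = "")), 0L)
  expect_identical(P1, P2)
  expect_false(identical(P1, P3))
})

test_that("single-permutation draws are uniform over distinct assignments", {
  # n = 4 choose 2 = 6 assignments; B = 1 draw across many seeds ~ uniform
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  draws <- vapply(1:2000, function(seed)
    paste(which(sam_permute(labels, 1, seed = seed)[, 1]), collapse = ","), "")
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("delta thresholding matches an exhaustive rank scan", {
  withr::with_seed(11, {
    expr <- rand_expr(20, 10, seed = 17)
    labels <- sample(rep(c(TRUE, FALSE), each = 5))
  })
  fit <- sam_fit(expr, labels, sam_config(n_permutations = 5, seed = 4,
                                          s0_mode = "value", s0_value = 0))
  for (delta in c(0, 0.1, 0.5, 1, 50)) {
    call <- sam_call_significant(fit, delta)
    oracle <- brute_force_cutpoints(fit$d, fit$dbar, delta)
    expect_equal(call$cut_up, oracle$cut_up)
    expect_equal(call$cut_low, oracle$cut_low)
    expect_equal(sort(call$significant_up), oracle$up)
    expect_equal(sort(call$significant_down), oracle$down)
  }
  huge <- sam_call_significant(fit, max(abs(sort(fit$d) - fit$dbar)) + 1)
  expect_equal(huge$n_called, 0L)
  expect_equal(huge$cut_up, Inf)
  expect_equal(huge$cut_low, -Inf)
})

test_that("pi0 follows its defining arithmetic and is ~1 under the null", {
  # all observed d outside the permuted IQR
  d_perm <- matrix(seq(-1, 1, length.out = 100), 2, 50)
  expect_equal(sam_estimate_pi0(c(5, 6, -7), d_perm), 0)
  # exactly half inside -> #inside / (0.5 n) caps at 1
  q <- stats::quantile(d_perm, c(0.25, 0.75))
  d_half <- c(rep(0, 5), rep(10, 5))
  expect_equal(sam_estimate_pi0(d_half, d_perm), 1)
  # complete null: pi0 near 1 over replicates
  pi0s <- vapply(1:20, function(seed) {
    expr <- rand_expr(200, 20, seed = seed)
    labels <- rep(c(TRUE, FALSE), each = 10)
    fit <- sam_fit(expr, labels, sam_config(seed = seed))
    fit$pi0
  }, 0)
  expect_gt(mean(pi0s), 1 - 3 * stats::sd(pi0s) / sqrt(length(pi0s)) - 0.1)
})

test_that("FDR estimate equals an exhaustive counting oracle", {
  expr <- rand_expr(50, 14, seed = 23)
  labels <- rep(c(TRUE, FALSE), each = 7)
  fit <- sam_fit(expr, labels, sam_config(n_permutations = 10, seed = 2))
  call <- sam_call_significant(fit, 0.2)
  if (call$n_called > 0) {
    V <- integer(nrow(fit$d_perm))
    for (b in seq_len(nrow(fit$d_perm)))        # brute-force tally
      for (i in seq_len(ncol(fit$d_perm)))
        if (fit$d_perm[b, i] >= call$cut_up || fit$d_perm[b, i] <= call$cut_low)
          V[b] <- V[b] + 1L
    expect_equal(call$fdr_estimate, fit$pi0 * stats::median(V) / call$n_called)
  }
  empty <- sam_call_significant(fit, 1e6)
  expect_equal(empty$fdr_estimate, 0)
})

test_that("run_sam recovers planted targets and respects the target FDR", {
  n_genes <- 200L; n <- 60L
  withr::with_seed(77, {
    expr <- matrix(stats::rnorm(n_genes * n), n_genes, n,
                   dimnames = list(sprintf("G%03d", 1:n_genes),
                                   sprintf("S%03d", 1:n)))
    labels <- rep(c(TRUE, FALSE), c(20, 40))
    targets <- sample(rownames(expr), 30)
    expr[targets, labels] <- expr[targets, labels] + 2
  })
  expr <- zscore_normalize(expr)
  res <- run_sam(expr, labels, sam_config(seed = 5))
  called <- c(res$significant_up, res$significant_down)
  expect_gte(length(intersect(called, targets)), 0.9 * length(targets))
  expect_lte(length(setdiff(called, targets)),
             max(1, 0.25 * length(called)))     # consistent with FDR 0.2
  expect_lte(res$fdr_estimate, 0.2)
  res2 <- run_sam(expr, labels, sam_config(seed = 5))
  expect_identical(res, res2)                    # determinism
})

test_that("untestable groups yield a typed signal, not a crash", {
  expr <- rand_expr(30, 10, seed = 9)
  res <- run_sam(expr, c(TRUE, TRUE, rep(FALSE, 8)), sam_config())
  expect_s3_class(res, "sam_untestable")
})

test_that("negating expression swaps up and down calls exactly", {
  withr::with_seed(13, {
    expr <- rand_expr(100, 24, seed = 19)
    labels <- sample(rep(c(TRUE, FALSE), each = 12))
    expr[1:10, labels] <- expr[1:10, labels] + 1.5
    expr[11:20, labels] <- expr[11:20, labels] - 1.5
  })
  cfg <- sam_config(seed = 3)
  a <- run_sam(expr, labels, cfg)
  b <- run_sam(-expr, labels, cfg)
  expect_setequal(a$significant_up, b$significant_down)
  expect_setequal(a$significant_down, b$significant_up)
})

test_that("n_called is nonincreasing in delta", {
  expr <- rand_expr(80, 20, seed = 29)
  labels <- rep(c(TRUE, FALSE), each = 10)
  fit <- sam_fit(expr, labels, sam_config(seed = 8))
  deltas <- seq(0, max(abs(sort(fit$d) - fit$dbar)), length.out = 20)
  counts <- vapply(deltas, function(dl) sam_call_significant(fit, dl)$n_called, 0L)
  expect_true(all(diff(counts) <= 0))
})
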