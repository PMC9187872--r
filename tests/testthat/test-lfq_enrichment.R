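mk_intensity <- function(vals) {
  m <- do.call(rbind, vals)
  colnames(m) <- paste0(rep(c("fl", "mut"), each = 5L), "_", rep(1:5, 2L))
  m
}
cond10 <- rep(c("fl", "mut"), each = 5L)

test_that("preprocessing: flags, the five-of-five rule, exclusivity", {
  m <- mk_intensity(list(
    full = 2^c(25, 25, 25, 25, 25, 24, 24, 24, 24, 24),
    excl = 2^c(25, 25, 25, 25, 25, NA, NA, NA, NA, NA),
    four = 2^c(25, 25, 25, 25, NA, 24, 24, 24, NA, 24),
    flagged = 2^rep(25, 10)))
  flags <- data.frame(reverse = c(FALSE, FALSE, FALSE, TRUE),
                      contaminant = FALSE, site = FALSE,
                      row.names = rownames(m))
  res <- lfq_preprocess(m, cond10, flags)
  expect_equal(rownames(res$log2), c("full", "excl"))
  expect_equal(res$dropped_flagged, "flagged")
  expect_equal(unname(res$exclusive), c(FALSE, TRUE))
  expect_equal(res$log2["full", 1L], 25)
  expect_error(lfq_preprocess(m[, 1:8], rep(c("fl", "mut"), each = 4L)),
               "5 vs 5")
})

test_that("imputation: only missing cells, correct moments, seeded", {
  set.seed(8)
  m <- matrix(rnorm(10100 * 2, 25, 1), 10100, 2)
  miss <- 101:10100
  m[miss, 1L] <- NA
  obs_mu <- mean(m[1:100, 1L]); obs_sd <- sd(m[1:100, 1L])
  imp <- lfq_impute(m, d = 2, w = 0.2, seed = 5)
  expect_equal(imp[1:100, ], m[1:100, ])      # observed untouched
  expect_equal(imp[, 2L], m[, 2L])
  vals <- imp[miss, 1L]
  se_mean <- 0.2 * obs_sd / sqrt(length(miss))
  expect_lt(abs(mean(vals) - (obs_mu - 2 * obs_sd)), 3 * se_mean)
  expect_equal(sd(vals), 0.2 * obs_sd, tolerance = 0.05)
  # determinism under seed; a complete matrix passes through unchanged
  expect_equal(imp, lfq_impute(m, seed = 5))
  expect_equal(lfq_impute(imp, seed = 1), imp)
  bad <- m; bad[2:10100, 1L] <- NA
  expect_error(lfq_impute(bad), "fewer than 2")
})

test_that("s0 = 0 statistic equals Student's pooled t exactly", {
  a <- c(0.9, 1.1, 1.0, 1.2, 0.8); b <- c(2.1, 1.9, 2.2, 1.8, 2.0)
  res <- s0_t_test(a, b, s0 = 0)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$d, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # 1000 seeded cases
  set.seed(71)
  for (k in 1:1000) {
    x <- rnorm(5, sd = runif(1, 0.5, 2)); y <- rnorm(5, mean = runif(1, -1, 1))
    r <- s0_t_test(x, y, s0 = 0)
    tt <- t.test(x, y, var.equal = TRUE)
    stopifnot(abs(r$d - tt$statistic) < 1e-10,
              abs(r$p - tt$p.value) < 1e-10)
  }
  succeed()
  # equal group means: d = 0, permutation p = 1
  r0 <- s0_t_test(c(1, 2, 3), c(3, 2, 1), s0 = 0.1)
  expect_equal(r0$d, 0)
  expect_equal(r0$p, 1)
  # d_s0 strictly decreases in s0 for a positive effect
  d_by_s0 <- vapply(c(0, 0.1, 0.5, 1), function(s)
    s0_t_test(b, a, s0 = s)$d, 0)
  expect_true(all(diff(d_by_s0) < 0))
  expect_error(s0_t_test(c(1, 1, 1), c(1, 1, 1), s0 = 0), "zero pooled")
})

test_that("permutation FDR: planted effects called, null controlled", {
  set.seed(301)
  n <- 500L
  m <- matrix(rnorm(n * 10L, 25, 1), n, 10L,
              dimnames = list(sprintf("p%03d", 1:n), NULL))
  shifted <- 1:10
  m[shifted, 6:10] <- m[shifted, 6:10] - 4  # 4 sigma shift in "mut"
  res <- permutation_fdr(m, cond10, numerator = "mut", denominator = "fl")
  expect_gte(sum(res$significant[shifted]), 8L)
  # permutation null leaves at most a handful of the 490 null proteins
  expect_lte(sum(res$significant[-(1:10)]), 5L)
  # volcano boundary samples exist and bracket the calls
  curve <- attr(res, "curve")
  expect_true(nrow(curve) > 0)
  expect_true(all(is.finite(curve$neg_log10_p)))

  # swapping the condition labels flips ratios but not the calls
  res2 <- permutation_fdr(m, cond10, numerator = "fl",
                          denominator = "mut")
  expect_equal(res2$log2_ratio, -res$log2_ratio)
  expect_equal(res2$significant, res$significant)
  expect_equal(attr(res2, "d_cut"), attr(res, "d_cut"))

  expect_error(permutation_fdr(m[, 1:9], cond10[1:9]), "balanced")
})

test_that("classification gates: worked example, fc gate, p gate", {
  # a bromodomain interactor at log2 -1.27, -log10 p 3.44: enriched
  expect_equal(classify_enrichment(-1.27, 3.44), "denominator")
  expect_equal(classify_enrichment(-0.5, 5), "none")        # fc gate
  expect_equal(classify_enrichment(-3, 2.0), "none")        # p = 0.01
  expect_equal(classify_enrichment(1.8, 4), "numerator")
  expect_equal(classify_enrichment(-1.27, p = 10^-3.44), "denominator")
  # boundary: exactly log2 ratio -1 or p = 0.002 is not enriched
  expect_equal(classify_enrichment(-1, 5), "none")
  expect_equal(classify_enrichment(-1.5, -log10(0.002)), "none")
})

test_that("compartment counts over the packaged interactor table", {
  tab <- read_interactor_table()
  expect_equal(nrow(tab), 48L)
  cc <- compartment_counts(tab)
  expect_equal(unname(cc["nuclear pore"]), 11L)
  expect_equal(unname(cc["nucleolus"]), 13L)
  expect_equal(unname(cc["nuclear lamin"]), 6L)
  # every listed interactor passes the enrichment filter
  expect_true(all(classify_enrichment(tab$log2_ratio, tab$neg_log10_p) ==
                    "denominator"))
  expect_equal(sum(tab$exclusive), 4L)
  empty <- compartment_counts(tab[0, , drop = FALSE])
  expect_equal(length(empty), 0L)
})

test_that("one-tailed t with Bonferroni adjustment", {
  set.seed(17)
  x <- rnorm(6, 2, 1)
  r <- one_tailed_t_bonferroni(x, mu0 = 0, m = 1L)
  expect_equal(r$p, r$p_adjusted)
  # closed-form oracle
  tor <- (mean(x) - 0) / (sd(x) / sqrt(6))
  expect_equal(r$t, tor)
  expect_equal(r$p, pt(tor, 5, lower.tail = FALSE))
  r3 <- one_tailed_t_bonferroni(x, mu0 = 0, m = 3L)
  expect_equal(r3$p_adjusted, min(1, 3 * r3$p))
  # symmetric values around mu0: t = 0, one-tailed p = 0.5
  r0 <- one_tailed_t_bonferroni(c(-1, 1, -2, 2), mu0 = 0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  expect_error(one_tailed_t_bonferroni(rep(1, 4), 0), "zero variance")
})
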