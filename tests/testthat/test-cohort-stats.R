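test_that("exact binomial prevalence reproduces closed-form values", {
  pr <- prevalence_test(39, 57)
  expect_equal(round(100 * pr$phat), 68)
  expect_equal(round(pr$p_two_sided, 3), 0.008)
  expect_equal(round(pr$ci_low, 2), 0.55)
  expect_equal(round(pr$ci_high, 2), 0.80)
  # Clopper-Pearson bounds agree with binom.test's interval
  bt <- binom.test(39, 57, 0.5)
  expect_equal(c(pr$ci_low, pr$ci_high), as.numeric(bt$conf.int),
               tolerance = 1e-10)
})

test_that("doubled-tail p matches full enumeration at small n", {
  # sum over all 2^10 outcomes: P(X >= 7) = 176/1024, doubled
  pr <- prevalence_test(7, 10)
  expect_equal(pr$p_two_sided, 2 * 176 / 1024)
  expect_equal(prevalence_test(5, 10)$p_two_sided, 1)  # k = n/2 exactly
  expect_equal(prevalence_test(57, 57)$ci_high, 1)
  expect_equal(prevalence_test(0, 57)$ci_low, 0)
  expect_error(prevalence_test(8, 5), "k")
})

test_that("Clopper-Pearson bounds are monotone in k", {
  n <- 57
  lows <- vapply(0:n, function(k) prevalence_test(k, n)$ci_low, numeric(1))
  highs <- vapply(0:n, function(k) prevalence_test(k, n)$ci_high, numeric(1))
  expect_true(all(diff(lows) >= 0))
  expect_true(all(diff(highs) >= 0))
  expect_true(all(lows <= (0:n) / n & (0:n) / n <= highs))
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)

  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 3)))$p, 1)

  set.seed(31)
  g <- list(rnorm(8), rnorm(9), rnorm(7))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(v) exp(v)))$H,
               tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(17)
  g1 <- round(rnorm(12), 1)  # rounding forces ties
  g2 <- round(rnorm(15, 0.8), 1)
  kw <- kruskal_wallis(list(g1, g2))
  mw <- mann_whitney(g1, g2)
  expect_equal(kw$H, mw$z^2, tolerance = 1e-6)
})

test_that("Dunn pairwise z agrees with the direct pooled-rank formula", {
  g <- list(a = c(1.2, 1.5, 1.7, 2.0, 2.1),
            b = c(5.1, 5.3, 6.0, 6.2, 7.0),
            c = c(3.0, 3.1, 3.3, 3.3, 3.9))
  pw <- dunn_pairwise_bonferroni(g)
  expect_equal(nrow(pw), 3L)
  for (i in seq_len(nrow(pw))) {
    ii <- match(pw$group1[i], names(g))
    jj <- match(pw$group2[i], names(g))
    expect_equal(pw$z[i], brute_dunn_z(g, ii, jj), tolerance = 1e-9)
  }
  expect_true(all(pw$p_adj <= 1))
  expect_equal(pw$p_adj, pmin(1, pw$p_unadj * 3))

  same <- dunn_pairwise_bonferroni(list(rep(1, 5), rep(1, 6)))
  expect_equal(same$z, 0)
  expect_equal(same$p_adj, 1)
  expect_error(dunn_pairwise_bonferroni(list(1:3, numeric(0))), "empty")
})

test_that("z converts to r with the pairwise sample size", {
  expect_equal(round(effect_size_r(6.60, 39 + 18), 2), 0.87)
  expect_equal(round(effect_size_r(4.38, 57), 2), 0.58)
  expect_equal(effect_size_r(0, 10), 0)
  expect_equal(effect_size_r(-2, 16), 0.5)
  expect_error(effect_size_r(1, 1), "n_pair")
})

test_that("Mann-Whitney exact p matches labeling enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_exact, 1 / 3)  # 2 of 6 labelings as extreme

  mw2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw2$U, 0)
  expect_equal(mw2$p_exact, 0.1)  # 2 of 20 labelings

  same <- mann_whitney(c(5, 5, 5), c(5, 5))
  expect_equal(same$U, 3 * 2 / 2)
  expect_equal(same$z, 0)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Friedman chi-square matches hand computation and base R", {
  # identical rows: fully tied
  fr0 <- friedman_stepdown(matrix(1, 5, 3))
  expect_equal(fr0$chi2, 0)
  expect_equal(fr0$p, 1)
  expect_length(fr0$homogeneous_subsets, 1L)
  expect_length(fr0$homogeneous_subsets[[1]], 3L)

  # 5 rows x 3 conditions, same strict order in every row: rank sums 5/10/15
  mat <- matrix(rep(c(1, 5, 9), each = 5), 5, 3) + matrix(runif(15, 0, 0.5), 5, 3)
  fr <- friedman_stepdown(mat)
  expect_equal(fr$chi2, 10, tolerance = 1e-12)
  expect_equal(fr$df, 2)

  # tie-free random matrix: agrees with stats::friedman.test
  set.seed(23)
  m2 <- matrix(rnorm(40), 8, 5)
  fr2 <- friedman_stepdown(m2)
  ref <- stats::friedman.test(m2)
  expect_equal(fr2$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(fr2$p, ref$p.value, tolerance = 1e-10)

  expect_error(friedman_stepdown(matrix(1, 5, 1)), "conditions")
  expect_error(friedman_stepdown(matrix(1, 1, 3)), "rows")
})

test_that("two-condition Friedman reduces to the sign-test statistic", {
  set.seed(41)
  for (rep_i in 1:10) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(2 * n), n, 2)
    fr <- friedman_stepdown(m)
    b <- sum(m[, 2] > m[, 1])
    a <- n - b
    expect_equal(fr$chi2, (b - a)^2 / n, tolerance = 1e-10)
  }
})

test_that("rows with missing ordinals are dropped and counted", {
  m <- matrix(rnorm(20), 5, 4)
  m[2, 3] <- NA
  fr <- friedman_stepdown(m)
  expect_equal(fr$n_used, 4L)
  expect_equal(fr$n_dropped, 1L)
})

test_that("step-down subsets isolate a clearly different condition", {
  set.seed(8)
  n <- 20
  m <- cbind(a = rnorm(n, 10), b = rnorm(n, 0), c = rnorm(n, 0.1))
  fr <- friedman_stepdown(m)
  expect_lt(fr$p, 0.05)
  subs <- fr$homogeneous_subsets
  expect_true(any(vapply(subs, function(s) setequal(s, c("b", "c")), TRUE)))
  expect_true(any(vapply(subs, function(s) identical(s, "a"), TRUE)))
})

test_that("descriptives use median, type-7 IQR and n-1 CV", {
  d <- descriptives(c(86, 86, 86))
  expect_equal(d$cv_percent, 0)
  d2 <- descriptives(c(80, 90, 100))
  expect_equal(d2$cv_percent, 100 * 10 / 90, tolerance = 1e-12)
  d3 <- descriptives(c(1, 2, 3, 4, 5))
  expect_equal(d3$median, 3)
  expect_equal(d3$iqr, 2)
  expect_warning(dz <- descriptives(c(-1, 1)), "CV undefined")
  expect_true(is.na(dz$cv_percent))
})

test_that("Kruskal-Wallis holds its nominal type-I error rate", {
  set.seed(12345)
  n_sim <- 10000
  rej <- 0L
  for (i in seq_len(n_sim)) {
    kw <- kruskal_wallis(list(rnorm(15), rnorm(15), rnorm(15)))
    if (kw$p < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_sim
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})
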