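toy_layout <- function() {
  classroom_layout(first_id = 1:4, second_id = 5:8,
                   class_id = c(1, 1, 2, 2))
}

test_that("pairings are uniform within class blocks and never cross them", {
  lay <- toy_layout()
  set.seed(61)
  draws <- t(replicate(10000, sample_pairing(lay)))
  # class constraint: first two dyads draw from {5,6}, last two from {7,8}
  expect_true(all(draws[, 1:2] %in% 5:6))
  expect_true(all(draws[, 3:4] %in% 7:8))
  # a 2-dyad class has exactly 2 pairings, each with frequency ~0.5
  tab <- table(draws[, 1])
  expect_gt(stats::chisq.test(tab, p = c(0.5, 0.5))$p.value, 0.01)
  # a single-dyad class admits only the true pairing
  solo <- classroom_layout(1, 2, 1)
  expect_identical(sample_pairing(solo), 2L)
})

test_that("identical feature vectors give a degenerate null at 1", {
  v <- c(1, 3, 2, 5, 4, 6)
  fs <- setNames(lapply(1:8, function(i) fake_fset(v)), as.character(1:8))
  mu <- null_distribution(fs, toy_layout(), "HR", n_permutations = 200,
                          seed = 1)
  expect_true(all(abs(mu - 1) < 1e-12))
})

test_that("Monte-Carlo null matches full block-permutation enumeration", {
  set.seed(63)
  lay <- toy_layout()
  fs <- setNames(lapply(1:8, function(i) fake_fset(rnorm(12))),
                 as.character(1:8))
  # oracle: enumerate all 2! x 2! = 4 block permutations
  vals <- vapply(fs, function(f) f$HR, numeric(12))
  enum <- c()
  for (p1 in list(c(5, 6), c(6, 5))) for (p2 in list(c(7, 8), c(8, 7))) {
    sec <- c(p1, p2)
    enum <- c(enum, mean(vapply(1:4, function(d) {
      brute_cor(vals[, d], vals[, sec[d]])
    }, numeric(1))))
  }
  mu <- null_distribution(fs, lay, "HR", n_permutations = 4000, seed = 2)
  se <- sd(enum) / sqrt(4000)
  expect_lt(abs(mean(mu) - mean(enum)), 3 * se + 1e-12)
  # every draw must equal one of the four enumerable values
  expect_true(all(vapply(mu, function(m) {
    any(abs(m - enum) < 1e-12)
  }, logical(1))))
})

test_that("null draws are reproducible under a fixed seed", {
  cls <- simulate_classroom(small_config(seed = 65))
  fs <- pipe_fsets(cls)
  a <- null_distribution(fs, cls$layout, "SDNN", n_permutations = 300,
                         seed = 99)
  b <- null_distribution(fs, cls$layout, "SDNN", n_permutations = 300,
                         seed = 99)
  expect_identical(a, b)
})

test_that("general (missing-window) path agrees with the fast path logic", {
  set.seed(67)
  lay <- toy_layout()
  vals <- lapply(1:8, function(i) rnorm(12))
  fs_full <- setNames(lapply(vals, fake_fset), as.character(1:8))
  # flag one window invalid for participant 1: forces the pairwise path
  valid <- rep(TRUE, 12); valid[4] <- FALSE
  fs_miss <- fs_full
  fs_miss[["1"]] <- fake_fset(vals[[1]], valid = valid)
  mu_miss <- null_distribution(fs_miss, lay, "HR", n_permutations = 100,
                               seed = 5)
  # oracle for one draw: recompute with masked windows dropped pairwise
  set.seed(5)
  sec <- sample_pairing(lay)
  r <- vapply(1:4, function(d) {
    a <- vals[[d]]; b <- vals[[sec[d]]]
    ok <- if (d == 1) valid else rep(TRUE, 12)
    brute_cor(a[ok], b[ok])
  }, numeric(1))
  expect_equal(mu_miss[1], mean(r), tolerance = 1e-12)
})

test_that("percentile CI uses linear interpolation", {
  u <- (1:10000) / 10000
  ci <- percentile_ci(u)
  expect_lt(abs(ci[1] - 0.025), 1e-3)
  expect_lt(abs(ci[2] - 0.975), 1e-3)
  cc <- percentile_ci(rep(0.4, 200))
  expect_equal(cc[1], cc[2])
  set.seed(69)
  z <- rnorm(10000)
  ci <- percentile_ci(z)
  expect_lt(abs(ci[1] + 1.96), 0.05)
  expect_lt(abs(ci[2] - 1.96), 0.05)
  expect_error(percentile_ci(rnorm(50)), "100")
})

test_that("two-tailed p follows the add-one smoothed formula", {
  s <- seq(-1, 1, length.out = 9999)
  expect_equal(two_tailed_p(0, s), 1)
  expect_equal(two_tailed_p(2, s), 2 / 10000)
  expect_equal(two_tailed_p(-2, s), 2 / 10000)
  # monotonicity of the upper tail component
  set.seed(71)
  s <- rnorm(500)
  ps <- vapply(seq(0, 3, by = 0.25), function(m) {
    (1 + sum(s >= m)) / 501
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("Holm-Bonferroni reproduces the hand-worked step-down values", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(c(0.02, 0.02, 0.02)), rep(0.06, 3))
  expect_error(holm_bonferroni(c(0.1, 1.2)), "0, 1")
  expect_error(holm_bonferroni(c(0.1, 0)), "0, 1")
})

test_that("spc_test assembles compliance, CI, and adjusted p per feature", {
  cls <- simulate_classroom(small_config(seed = 73))
  fs <- pipe_fsets(cls)
  tst <- spc_test(fs, cls$layout, n_permutations = 300, seed = 4)
  tab <- tst$table
  expect_equal(tab$feature, c("HR", "SDNN", "rMSSD"))
  expect_true(all(tab$ci_lo <= tab$ci_hi))
  expect_true(all(tab$p_raw > 0 & tab$p_raw <= 1))
  expect_true(all(tab$p_adjusted >= tab$p_raw - 1e-12))
  expect_equal(tab$p_adjusted, holm_bonferroni(tab$p_raw))
  expect_equal(length(tst$mu_samples$SDNN), 300)
  # determinism of the whole test object
  tst2 <- spc_test(fs, cls$layout, n_permutations = 300, seed = 4)
  expect_identical(tst$table, tst2$table)
})
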