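make_reports <- function(lay, seed = 1) {
  set.seed(seed)
  ids <- c(lay$first_id, lay$second_id)
  out <- data.frame(participant_id = ids)
  for (it in c("MD", "TD", "Pe", "Ef", "Fr", "Na")) {
    out[[it]] <- sample(0:10, length(ids), replace = TRUE)
  }
  out
}

test_that("dyad sums are itemwise member sums within range", {
  lay <- classroom_layout(1:3, 4:6, c(1, 1, 1))
  rep_df <- make_reports(lay, seed = 2)
  sums <- dyad_sums(rep_df, lay)
  for (it in c("MD", "TD", "Pe", "Ef", "Fr", "Na")) {
    expect_equal(sums[[it]],
                 rep_df[[it]][match(lay$first_id, rep_df$participant_id)] +
                   rep_df[[it]][match(lay$second_id, rep_df$participant_id)])
    expect_true(all(sums[[it]] >= 0 & sums[[it]] <= 20))
  }
  zero <- rep_df; zero[, -1] <- 0L
  expect_true(all(as.matrix(dyad_sums(zero, lay)[, -1]) == 0))
  ten <- rep_df; ten[, -1] <- 10L
  expect_true(all(as.matrix(dyad_sums(ten, lay)[, -1]) == 20))
})

test_that("missing reports and items are reported by dyad and item", {
  lay <- classroom_layout(1:3, 4:6, c(1, 1, 1))
  rep_df <- make_reports(lay, seed = 3)
  expect_error(dyad_sums(rep_df[-2, ], lay), "2")
  bad <- rep_df; bad$TD[4] <- NA
  expect_error(dyad_sums(bad, lay), "TD")
  expect_error(dyad_sums(rep_df[, -3], lay), "TD")
})

test_that("regression coefficients match a normal-equations solve", {
  set.seed(81)
  for (i in 1:5) {
    lay <- classroom_layout(1:19, 20:38, rep(1:4, c(5, 5, 5, 4)))
    sums <- dyad_sums(make_reports(lay, seed = 100 + i), lay)
    r <- rnorm(19)
    fit <- spc_lm(sums, r)
    X <- cbind(1, as.matrix(sums[, c("MD", "TD", "Pe", "Ef", "Fr", "Na")]))
    beta <- solve(t(X) %*% X, t(X) %*% r)
    expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-9)
    # predictions + residuals reconstruct the response exactly
    expect_equal(unname(fitted(fit) + residuals(fit)), r, tolerance = 1e-12)
  }
})

test_that("an exactly linear response is fit perfectly", {
  lay <- classroom_layout(1:10, 11:20, rep(1, 10))
  sums <- dyad_sums(make_reports(lay, seed = 7), lay)
  r <- 0.5 - 0.03 * sums$TD
  # a zero-residual fit makes summary.lm warn about perfect fits
  fit <- suppressWarnings(spc_lm(sums, r))
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1)
  cf <- coef(fit)
  expect_equal(unname(cf["TD"]), -0.03, tolerance = 1e-10)
  expect_equal(unname(cf[c("MD", "Pe", "Ef", "Fr", "Na")]), rep(0, 5),
               tolerance = 1e-10)
})

test_that("fit is invariant to dyad row order", {
  lay <- classroom_layout(1:12, 13:24, rep(1:2, each = 6))
  sums <- dyad_sums(make_reports(lay, seed = 11), lay)
  set.seed(12)
  r <- rnorm(12)
  f1 <- spc_lm(sums, r)
  perm <- sample(12)
  f2 <- spc_lm(sums[perm, ], r[perm])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(f1$adj_r2, f2$adj_r2, tolerance = 1e-12)
})

test_that("degenerate designs raise informative errors", {
  lay <- classroom_layout(1:6, 7:12, rep(1, 6))
  sums <- dyad_sums(make_reports(lay, seed = 13), lay)
  expect_error(spc_lm(sums, rnorm(6)), "at least 8")
  lay2 <- classroom_layout(1:10, 11:20, rep(1, 10))
  sums2 <- dyad_sums(make_reports(lay2, seed = 14), lay2)
  sums2$Na <- sums2$MD            # exact collinearity
  expect_error(spc_lm(sums2, rnorm(10)), "collinear")
})

test_that("adjusted R-squared is unbiased near zero under the null", {
  set.seed(83)
  lay <- classroom_layout(1:19, 20:38, rep(1:4, c(5, 5, 5, 4)))
  sums <- dyad_sums(make_reports(lay, seed = 15), lay)
  a2 <- replicate(500, spc_lm(sums, rnorm(19))$adj_r2)
  expect_lt(abs(mean(a2)), 0.05)
})

test_that("a configured negative temporal-demand effect is sign-recovered", {
  # full pipeline per replicate: beats -> NN -> windowed SDNN compliance,
  # regressed on the generated temporal-demand dyad sums
  neg <- logical(30)
  for (i in seq_along(neg)) {
    cls <- simulate_classroom(classroom_config(
      tlx_temporal_effect = -10, seed = 60000 + i))
    comp <- spc_compliance(pipe_fsets(cls), cls$layout, "SDNN")
    sums <- dyad_sums(cls$reports, cls$layout)
    neg[i] <- coef(lm(comp$per_dyad$r ~ sums$TD))[2] < 0
  }
  expect_gte(mean(neg), 0.9)
})

test_that("population item means recover participant-level averages", {
  d <- study_dyads()
  expect_equal(population_item_mean(d, "MD"), 229 / 38, tolerance = 1e-12)
  expect_equal(population_item_mean(d, "Na"), 309 / 38, tolerance = 1e-12)
  z <- data.frame(MD = c(0, 0))
  expect_equal(population_item_mean(z, "MD"), 0)
  expect_error(population_item_mean(d, "XX"), "unknown item")
})
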