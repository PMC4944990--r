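test_that("identical configs reproduce bitwise-identical classrooms", {
  a <- simulate_classroom(small_config(seed = 42))
  b <- simulate_classroom(small_config(seed = 42))
  expect_identical(a$beats, b$beats)
  expect_identical(a$reports, b$reports)
  expect_identical(a$truth$coupling, b$truth$coupling)
})

test_that("generated beat series satisfy the physiological invariants", {
  cls <- simulate_classroom(small_config(seed = 7))
  expect_length(cls$beats, 2 * sum(small_config()$n_dyads_per_class))
  for (b in cls$beats) {
    d <- diff(b)
    expect_true(all(d > 0))
    expect_true(all(d * 1000 > 300 & d * 1000 < 2000))
    expect_lte(max(b), small_config()$session_length_s)
  }
  # first-member/second-member id convention: j = i + n_dyads
  lay <- cls$layout
  expect_identical(lay$second_id, lay$first_id + nrow(lay))
  expect_identical(lay$class_id[match(lay$first_id, lay$first_id)],
                   lay$class_id)
  # reports are integers on the 0-10 scale
  for (it in c("MD", "TD", "Pe", "Ef", "Fr", "Na")) {
    expect_true(all(cls$reports[[it]] >= 0 & cls$reports[[it]] <= 10))
    expect_type(cls$reports[[it]], "integer")
  }
})

test_that("invalid configurations are rejected", {
  expect_error(classroom_config(coupling = 1.2), "coupling")
  expect_error(classroom_config(coupling = -0.1), "coupling")
  expect_error(classroom_config(session_length_s = 200), "session_length_s")
  expect_error(classroom_config(base_ibi_ms = 250), "base_ibi_ms")
  expect_error(classroom_config(n_dyads_per_class = integer(0)),
               "n_dyads_per_class")
  expect_error(simulate_classroom(list()), "classroom_config")
})

test_that("uncoupled dyads show no SDNN compliance on average", {
  # kappa = 0 and no trend: expected dyad SDNN correlation is zero
  rs <- c()
  for (i in 1:40) {
    cls <- simulate_classroom(classroom_config(
      n_dyads_per_class = c(3, 3), session_length_s = 3600,
      coupling = 0, hr_trend_slope_bpm_per_min = 0, seed = 100 + i))
    comp <- spc_compliance(pipe_fsets(cls), cls$layout, "SDNN")
    rs <- c(rs, comp$per_dyad$r)
  }
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("stronger coupling yields larger mean SDNN compliance", {
  mu_at <- function(kappa, seeds) {
    mean(vapply(seeds, function(s) {
      cls <- simulate_classroom(classroom_config(
        n_dyads_per_class = c(3, 3), session_length_s = 3600,
        coupling = kappa, seed = s))
      spc_compliance(pipe_fsets(cls), cls$layout, "SDNN")$mu_true
    }, numeric(1)))
  }
  hi <- mu_at(0.9, 1:20)
  lo <- mu_at(0.1, 21:40)
  expect_gt(hi, lo)
  expect_gt(hi, 0.4)   # strong coupling must show substantial compliance
})

test_that("temporal demand decreases with coupling; other items do not", {
  td <- kap <- md <- c()
  for (i in 1:25) {
    cls <- simulate_classroom(classroom_config(
      n_dyads_per_class = c(5, 5), session_length_s = 400, seed = 300 + i))
    sums <- dyad_sums(cls$reports, cls$layout)
    td <- c(td, sums$TD); md <- c(md, sums$MD)
    kap <- c(kap, cls$truth$coupling)
  }
  b_td <- coef(lm(td ~ kap))[2]
  expect_lt(b_td, -2)       # configured dyad-sum gradient is -6
  expect_gt(b_td, -10)
  # mental demand carries no coupling signal beyond sampling noise
  expect_lt(abs(coef(lm(md ~ kap))[2]), abs(b_td))
})

test_that("most dyads express a shared negative heart-rate trend", {
  frac <- vapply(1:6, function(i) {
    cls <- simulate_classroom(classroom_config(seed = 400 + i))
    fs <- pipe_fsets(cls)
    sl <- vapply(fs, function(f) linear_trend(f, "HR")$slope, numeric(1))
    lay <- cls$layout
    mean(sl[as.character(lay$first_id)] < 0 &
           sl[as.character(lay$second_id)] < 0)
  }, numeric(1))
  # trend_participation 0.8 with sign-random non-trenders: expect ~0.81
  expect_gt(mean(frac), 0.65)
  expect_lt(mean(frac), 0.95)
})

test_that("synthetic ECG centres a dominant deflection at each beat", {
  set.seed(5)
  ecg <- synthesize_ecg(c(1, 2, 3), sampling_rate = 500)
  for (b in c(1, 2, 3)) {
    win <- which(abs(ecg$time_s - b) <= 0.3)
    tmax <- ecg$time_s[win][which.max(ecg$samples[win])]
    expect_lt(abs(tmax - b), 0.010)
  }
  # degenerate input: noise-only trace
  flat <- synthesize_ecg(numeric(0), sampling_rate = 250)
  expect_lt(max(abs(flat$samples)), 0.5)
  expect_error(synthesize_ecg(c(2, 1), 250), "increasing")
  expect_error(synthesize_ecg(c(1, 2), 50), "sampling_rate")
})
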