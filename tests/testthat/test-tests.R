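make_competing_fixture <- function(n = 150, a1 = 1, a2 = 1, tau = 0.5,
                                   seed = 1) {
  withr::local_seed(seed)
  lambda <- a1 + a2
  tt <- rexp(n, lambda)
  cause <- ifelse(runif(n) < a1 / lambda, "1", "2")
  rec <- event_records(seq_len(n), 0, tt, "0", cause)
  list(cd1 = build_counting_data(rec, "0", "1", tau = tau, n = n),
       cd2 = build_counting_data(rec, "0", "2", tau = tau, n = n))
}

test_that("the within-sample KS statistic matches hand computation", {
  fit <- toy_fit()
  cd_none <- build_counting_data(toy_records(), "0", "1", tau = 3, n = 3)
  fit_none <- na_fit(cd_none)
  d1 <- wild_bootstrap_paths(toy_cd(), multiplier_spec("normal", 1), B = 300)
  d2 <- wild_bootstrap_paths(cd_none, multiplier_spec("normal", 1),
                             stream = 1, B = 300)
  res <- ks_equality_test(fit, fit_none, d1, d2, interval = c(0, 3))
  expect_equal(res$statistic, sqrt(3) * 5 / 6)

  # identical fits: statistic 0, never rejected against a positive quantile
  res0 <- ks_equality_test(fit, fit, d1, d2, interval = c(0, 3))
  expect_equal(res0$statistic, 0)
  expect_false(res0$reject)
  expect_error(ks_equality_test(fit, na_fit(build_counting_data(
    toy_records(), "0", "2", tau = 3, n = 7)), d1, d2,
    interval = c(0, 3)), "share n")
})

test_that("p-values and rejections agree away from the quantile boundary", {
  fx <- make_competing_fixture(seed = 5)
  f1 <- na_fit(fx$cd1); f2 <- na_fit(fx$cd2)
  for (s in 1:6) {
    d1 <- wild_bootstrap_paths(fx$cd1, multiplier_spec("normal", s), B = 199)
    d2 <- wild_bootstrap_paths(fx$cd2, multiplier_spec("normal", s), B = 199)
    res <- ks_equality_test(f1, f2, d1, d2, interval = c(0, 0.5))
    if (abs(res$p_value - res$alpha) > 1 / (res$B + 1)) {
      expect_equal(res$reject, res$p_value < res$alpha)
    }
    expect_gte(res$p_value, 1 / (res$B + 1))   # add-one rule: never 0
  }
})

test_that("equivalence by band inclusion is strict and margin-monotone", {
  a_t <- step_function(c(1, 2), c(0.3, 0.8))
  # band identical to the reference with unit margins: strictly inside
  m <- equivalence_margins(a_t, 1, 1)
  res <- equivalence_test(a_t, a_t, m, c(1, 2.5))
  expect_true(res$reject)
  expect_lt(res$statistic, 0)

  # upper limit touching A0 + u at one point: strictness forbids rejection
  touch <- step_function(c(1, 2), c(0.3 + 1, 0.8))
  res_touch <- equivalence_test(a_t, touch, m, c(1, 2.5))
  expect_false(res_touch$reject)

  # margins shrunk toward zero never reject
  m_small <- equivalence_margins(a_t, 1e-9, 1e-9)
  lo <- step_function(c(1, 2), c(0.29, 0.79))
  hi <- step_function(c(1, 2), c(0.31, 0.81))
  expect_false(equivalence_test(lo, hi, m_small, c(1, 2.5))$reject)
  expect_error(equivalence_margins(a_t, -1, 1), "strictly positive")
})

test_that("band limits feed the equivalence test end to end", {
  rec <- simulate_survival(300, hazard = 1, cens_at = Inf, seed = 61)
  cd <- build_counting_data(rec, "0", "1", tau = 1, n = 300)
  fit <- na_fit(cd)
  d <- wild_bootstrap_paths(cd, multiplier_spec("normal", 62), B = 500)
  band <- na_confidence_band(fit, band_spec("HW_w", 0.05, c(0.2, 1)),
                             draws = d)
  lim <- band_limits(band)
  expect_equal(eval_step(lim$lower, band$times), band$lower)
  # truth A0(t) = t with generous margins: equivalence established
  wide <- equivalence_margins(function(s) s, 0.6, 0.6)
  expect_true(equivalence_test(lim$lower, lim$upper, wide,
                               c(0.2, 1))$reject)
  # margins narrower than the band width: cannot establish equivalence
  narrow <- equivalence_margins(function(s) s, 0.01, 0.01)
  expect_false(equivalence_test(lim$lower, lim$upper, narrow,
                                c(0.2, 1))$reject)
})

test_that("proportional samples yield a zero proportionality statistic", {
  fx <- make_competing_fixture(seed = 8)
  cd1 <- fx$cd1
  # sample 2 = duplicated sample (doubled jump sizes and risk sets):
  # Ahat2 / Ahat1 is exactly constant, so both statistics vanish
  cd2 <- cd1
  cd2$delta_n <- 2L * cd1$delta_n
  cd2$y <- 2L * cd1$y
  cd2$n <- 2L * cd1$n
  for (rho in c("KS", "CvM")) {
    res <- proportionality_test(cd1, cd2, rho, B = 100,
                                spec = multiplier_spec("normal", 3))
    expect_equal(res$statistic, 0)
    expect_false(res$reject)
  }
})

test_that("the proportionality test rejects a crossing-hazards alternative", {
  # group 1: constant hazard; group 2: strongly time-increasing hazard
  # (Weibull shape 3) with a similar cumulative level -> non-proportional
  withr::local_seed(99)
  n <- 1000
  r1 <- event_records(seq_len(n), 0, rexp(n, 2), "0", "1")
  r2 <- event_records(seq_len(n), 0, 0.45 * rweibull(n, 3, 1), "0", "1")
  cd1 <- build_counting_data(r1, "0", "1", tau = 0.3, n = n)
  cd2 <- build_counting_data(r2, "0", "1", tau = 0.3, n = n)
  hits <- 0
  for (s in 1:4) {
    res <- proportionality_test(cd1, cd2, "KS", B = 400,
                                spec = multiplier_spec("normal", s))
    hits <- hits + res$reject
  }
  expect_gt(hits / 4, 0.5)
})

test_that("two-sample equality statistic scales at the root-n rate", {
  fx <- make_competing_fixture(seed = 12)
  res <- ks_two_sample_equality_test(fx$cd1, fx$cd2, B = 100,
                                     spec = multiplier_spec("normal", 7))
  # duplicating both samples doubles n1 n2 / n: statistic scales by sqrt(2)
  dup <- function(cd) {
    cd$delta_n <- 2L * cd$delta_n
    cd$y <- 2L * cd$y
    cd$n <- 2L * cd$n
    cd
  }
  res2 <- ks_two_sample_equality_test(dup(fx$cd1), dup(fx$cd2), B = 100,
                                      spec = multiplier_spec("normal", 7))
  expect_equal(res2$statistic, sqrt(2) * res$statistic)

  # identical samples: statistic exactly 0
  res0 <- ks_two_sample_equality_test(fx$cd1, fx$cd1, B = 100,
                                      spec = multiplier_spec("normal", 7))
  expect_equal(res0$statistic, 0)
})

test_that("test results serialise to JSON lines", {
  fx <- make_competing_fixture(seed = 13)
  res <- ks_two_sample_equality_test(fx$cd1, fx$cd2, B = 50,
                                     spec = multiplier_spec("normal", 9))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_test_result(res, path)
  rec <- jsonlite::fromJSON(readLines(path))
  expect_equal(rec$statistic, res$statistic)
  expect_equal(rec$reject, res$reject)
  expect_equal(rec$B, 50)
})
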