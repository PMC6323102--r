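test_that("the variance-stabilising transform maps onto [0, 1)", {
  f <- step_function(c(1, 2, 3), c(0, 1, 13 / 12))
  ph <- phi_hat(f)
  expect_equal(ph$values, c(0, 0.5, 13 / 25))
  expect_error(phi_hat(step_function(1, -0.1)), "nonnegative")
})

test_that("brownian-bridge critical values match analytic oracles", {
  # degenerate interval: B0(phi) ~ N(0, phi(1 - phi))
  expect_equal(bb_critical_value("g2", 0.5, 0.5, 0.05, 4e4, seed = 2),
               qnorm(0.975) * sqrt(0.25), tolerance = 0.02)
  # g1 cancels the standard deviation: normal quantile for any phi
  for (phi in c(0.2, 0.7)) {
    expect_equal(bb_critical_value("g1", phi, phi, 0.05, 4e4, seed = 3),
                 qnorm(0.975), tolerance = 0.03)
  }
  # full-interval unweighted sup: Kolmogorov distribution
  kq <- kolmogorov_quantile(0.95)
  expect_equal(kq, 1.3581, tolerance = 1e-4)
  expect_equal(bb_critical_value("g2", 0, 1, 0.05, n_paths = 3e4,
                                 grid = 300, seed = 4),
               kq, tolerance = 0.02)
  expect_error(bb_critical_value("g1", 0, 0.9, 0.05), "unbounded")
})

test_that("wild-bootstrap critical values apply the band transform", {
  # single draw, single jump, What = 1, sigma^2 = 1, g2: sup = 1/2
  rec <- event_records("a", 0, 1, "0", "1")
  cd <- build_counting_data(rec, "0", "1", tau = 1, n = 1)
  d <- wild_bootstrap_paths(cd, B = 1, multipliers = matrix(1, 1, 1))
  v1 <- step_function(1, 1)
  expect_equal(wb_critical_value(d, "g2", v1, 0.5, c(0, 1)), 0.5)
  # identity transform realises the linear-band quantile rule
  cdt <- toy_cd()
  dd <- wild_bootstrap_paths(cdt, B = 4,
                             multipliers = rbind(c(0.1, 0), c(0.2, 0),
                                                 c(0.3, 0), c(0.4, 0)))
  expect_equal(wb_critical_value(dd, "none", alpha = 0.25,
                                 interval = c(0, 3)),
               0.3 * sqrt(3) / 3)
  d0 <- wild_bootstrap_paths(cdt, B = 3, multipliers = matrix(0, 3, 2))
  expect_equal(wb_critical_value(d0, "g2", aalen_variance(cdt), 0.05,
                                 c(0, 3)), 0)
  expect_error(wb_critical_value(d0, "g1", step_function(1, 0), 0.05,
                                 c(0, 3)), "phi")
})

test_that("band formulas back-transform the toy fixture correctly", {
  fit <- toy_fit()
  spec_ep <- band_spec("EP_w", 0.05, c(1, 2.5), variance_source = "aalen")
  b <- build_band(fit, 2, spec_ep)
  i2 <- which(b$times == 2)
  expect_equal(b$lower[i2], 5 / 6 * exp(-2 * sqrt(13 / 12) /
                                          (sqrt(3) * 5 / 6)))
  expect_equal(b$lower[i2], 0.1970, tolerance = 1e-4)
  expect_equal(b$upper[i2], 3.5253, tolerance = 1e-4)

  # zero critical value collapses every band onto the estimate
  for (bt in c("EP_w", "HW_w", "dir_w")) {
    sp <- band_spec(bt, 0.05, c(1, 2.5),
                    variance_source = if (bt == "dir_w") NULL else "aalen")
    b0 <- build_band(fit, 0, sp)
    expect_equal(b0$lower, b0$estimate)
    expect_equal(b0$upper, b0$estimate)
  }

  bd <- build_band(fit, 0.5, band_spec("dir_w", 0.05, c(1, 2.5)))
  expect_equal(bd$upper - bd$estimate, rep(0.5 / sqrt(3), 2))

  # transformed bands need an event before t1
  expect_error(build_band(fit, 1, band_spec("EP_w", 0.05, c(0.5, 2.5),
                                            variance_source = "aalen")),
               "move t1")
})

test_that("bands contain the estimate and respect their positivity class", {
  rec <- simulate_survival(120, hazard = 1, cens_at = 1.2, seed = 9)
  cd <- build_counting_data(rec, "0", "1", tau = 1)
  fit <- na_fit(cd)
  d <- wild_bootstrap_paths(cd, multiplier_spec("normal", 10), B = 500)
  for (bt in c("EP_w", "HW_w", "dir_w", "EP_a", "HW_a")) {
    sp <- band_spec(bt, 0.05, c(0.15, 1), B = 500, bb_paths = 500,
                    bb_grid = 300)
    b <- na_confidence_band(fit, sp, draws = d)
    expect_true(all(b$lower <= b$estimate + 1e-12))
    expect_true(all(b$upper >= b$estimate - 1e-12))
    if (bt != "dir_w") expect_true(all(b$lower > 0))
  }
})

test_that("brownian-bridge and wild-bootstrap widths agree at large n", {
  rec <- simulate_survival(1500, hazard = 1, cens_at = Inf, seed = 12)
  cd <- build_counting_data(rec, "0", "1", tau = 1)
  fit <- na_fit(cd)
  d <- wild_bootstrap_paths(cd, multiplier_spec("normal", 13), B = 2000)
  widths <- function(b) b$upper - b$lower
  for (shape in c("HW", "EP")) {
    sp_a <- band_spec(paste0(shape, "_a"), 0.05, c(0.2, 1),
                      bb_paths = 4000, bb_grid = 500)
    sp_w <- band_spec(paste0(shape, "_w"), 0.05, c(0.2, 1), B = 2000)
    b_a <- na_confidence_band(fit, sp_a)
    b_w <- na_confidence_band(fit, sp_w, draws = d)
    rel <- median(abs(widths(b_a) - widths(b_w)) / widths(b_w))
    expect_lt(rel, 0.1)
  }
})

test_that("difference bands degenerate correctly", {
  fit <- toy_fit()
  d <- wild_bootstrap_paths(toy_cd(), multiplier_spec("normal", 3), B = 200)
  # identical replicate draws: zero-width band around 0
  b <- difference_band(fit, fit, d, d, 0.05, c(0, 3))
  expect_equal(b$critical_value, 0)
  expect_equal(b$lower, b$upper)
  expect_equal(b$estimate, rep(0, length(b$times)))

  # an empty second transition reduces q to the one-sample linear quantile
  cd_none <- build_counting_data(toy_records(), "0", "1", tau = 3, n = 3)
  d_none <- wild_bootstrap_paths(cd_none, multiplier_spec("normal", 4),
                                 B = 200)
  fit_none <- na_fit(cd_none)
  b2 <- difference_band(fit, fit_none, d, d_none, 0.05, c(0, 3))
  expect_equal(b2$critical_value,
               wb_critical_value(d, "none", alpha = 0.05,
                                 interval = c(0, 3)))
  expect_error(difference_band(fit, na_fit(build_counting_data(
    toy_records(), "0", "2", tau = 3, n = 5)), d, d, 0.05, c(0, 3)),
    "share n")
})

test_that("simultaneous intervals reduce to and dominate pointwise ones", {
  rec <- simulate_survival(100, hazard = 1, cens_at = Inf, seed = 15)
  cd <- build_counting_data(rec, "0", "1", tau = 1)
  fit <- na_fit(cd)
  d <- wild_bootstrap_paths(cd, multiplier_spec("normal", 16), B = 400)
  one <- simultaneous_intervals(fit, d, 0.5, 0.05)
  two <- simultaneous_intervals(fit, d, c(0.5, 0.9), 0.05)
  expect_gte(attr(two, "critical_value"), attr(one, "critical_value"))
  # full jump grid: critical value equals the band's
  full <- simultaneous_intervals(fit, d, cd$times[cd$times <= 1], 0.05)
  band_cv <- wb_critical_value(d, "none", alpha = 0.05, interval = c(0, 1))
  expect_equal(attr(full, "critical_value"), band_cv)
  expect_error(simultaneous_intervals(fit, d, numeric(0), 0.05),
               "at least one")
})

test_that("sidak regions widen each component as k grows", {
  rec <- simulate_survival(100, hazard = 1, cens_at = Inf, seed = 17)
  cd <- build_counting_data(rec, "0", "1", tau = 1)
  fit <- na_fit(cd)
  d <- wild_bootstrap_paths(cd, multiplier_spec("normal", 18), B = 400)
  r1 <- sidak_region(list(fit), list(d), 0.5, 0.05)
  expect_equal(r1$level_each, 0.95)
  r2 <- sidak_region(list(fit, fit), list(d, d), 0.5, 0.05)
  expect_equal(unique(r2$level_each), 0.95^(1 / 2))
  expect_true(all(r2$lower <= r1$lower) && all(r2$upper >= r1$upper))
})

test_that("band files round-trip their metadata header", {
  fit <- toy_fit()
  b <- build_band(fit, 2, band_spec("EP_w", 0.05, c(1, 2.5),
                                    variance_source = "aalen"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_band(b, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# band_type: EP_w", lines)))
  expect_true(any(grepl("^# critical_value: 2", lines)))
  df <- read.csv(path, comment.char = "#")
  expect_equal(df$time, b$times)
  expect_equal(df$lower, b$lower)
})
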