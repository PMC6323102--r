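#' Variance-stabilising time transformation
#'
#' `phi(t) = sigma^2(t) / (1 + sigma^2(t))`, the time transformation that
#' maps the limiting Gaussian martingale of the normalized Nelson-Aalen
#' process onto a Brownian bridge; values lie in `[0, 1)`.
#'
#' @param variance a nonnegative [step_function()] variance estimate.
#' @return a [step_function()].
#' @export
phi_hat <- function(variance) {
  stopifnot(inherits(variance, "step_function"))
  if (any(variance$values < 0)) stop("variance must be nonnegative")
  step_function(variance$times, variance$values / (1 + variance$values))
}

# Sample the in-cell maximum of a Brownian bridge running from a to b over
# a time step dt (unit diffusion), via the closed-form conditional law
# P(M >= x | a, b) = exp(-2 (x - a)(x - b) / dt).
bridge_cell_max <- function(a, b, dt) {
  u <- stats::runif(length(a))
  0.5 * (a + b + sqrt((a - b)^2 - 2 * dt * log(u)))
}

# Band weight functions: g1 equalises pointwise precision, g2 is constant.
g_weight <- function(g, s) {
  switch(g,
         g1 = 1 / sqrt(s * (1 - s)),
         g2 = rep(1, length(s)),
         none = rep(1, length(s)),
         stop("unknown weight id: ", g))
}

#' Brownian-bridge critical value
#'
#' Monte-Carlo `(1 - alpha)` quantile of
#' `sup_{s in [phi_lo, phi_hi]} | g(s) B0(s) |` for a standard Brownian
#' bridge B0, the asymptotic calibration of the equal-precision (`g = "g1"`)
#' and Hall-Wellner (`g = "g2"`) bands.  The bridge is simulated exactly on
#' a uniform grid over `[phi_lo, phi_hi]` through the Markov conditional
#' recursion (exact Gaussian marginals at every grid point), in memory
#' chunks; a degenerate interval (`phi_lo == phi_hi`) uses the exact normal
#' marginal `B0(phi) ~ N(0, phi (1 - phi))` with no grid at all.
#'
#' With `refine = TRUE` (the default) the supremum inside each grid cell is
#' sampled from the closed-form law of the extremes of the conditioned
#' in-cell bridge, removing the downward discretization bias of a plain
#' grid maximum (the weight is frozen at its larger cell-endpoint value,
#' exact for `g2` and slightly conservative for `g1` on a fine grid).
#'
#' @param g weight id, `"g1"` or `"g2"`.
#' @param phi_lo,phi_hi transformed interval endpoints,
#'   `0 <= phi_lo <= phi_hi <= 1` (`g1` requires both strictly inside
#'   `(0, 1)`, since its weight is unbounded at the ends).
#' @param alpha level in (0, 1).
#' @param n_paths number of simulated bridge paths.
#' @param grid number of uniform grid points.
#' @param seed RNG seed.
#' @return a single numeric critical value.
#' @examples
#' bb_critical_value("g2", 0, 1, 0.05, n_paths = 2000, grid = 500, seed = 1)
#' @export
bb_critical_value <- function(g = c("g2", "g1"), phi_lo, phi_hi,
                              alpha = 0.05, n_paths = 1000L, grid = 1000L,
                              seed = 1L, refine = TRUE) {
  g <- match.arg(g)
  stopifnot(phi_lo >= 0, phi_hi >= phi_lo, phi_hi <= 1,
            alpha > 0, alpha < 1, n_paths >= 1, grid >= 2)
  if (g == "g1" && (phi_lo <= 0 || phi_hi >= 1)) {
    stop("the equal-precision weight g1 is unbounded at 0 and 1; ",
         "restrict the interval to phi values strictly inside (0, 1)")
  }
  if (phi_lo == phi_hi) {
    phi <- phi_lo
    if (phi == 0 || phi == 1) return(0)   # B0 degenerates to 0 there
    sups <- with_seed(seed, abs(g_weight(g, phi) *
                                  stats::rnorm(n_paths,
                                               sd = sqrt(phi * (1 - phi)))))
    return(bootstrap_quantile(sups, alpha))
  }
  ts <- seq(phi_lo, phi_hi, length.out = grid)
  gv <- g_weight(g, ts)
  gv[ts == 0 | ts == 1] <- 0               # B0 is a.s. 0 at the ends
  with_seed(seed, {
    sups <- numeric(0)
    remaining <- n_paths
    chunk_size <- max(1L, min(n_paths, as.integer(2e4)))
    while (remaining > 0L) {
      P <- min(chunk_size, remaining)
      t_prev <- ts[1]
      b <- if (t_prev >= 1) numeric(P) else
        stats::rnorm(P, sd = sqrt(t_prev * (1 - t_prev)))
      smax <- abs(gv[1] * b)
      for (i in 2:grid) {
        ti <- ts[i]
        b_prev <- b
        if (1 - t_prev <= 0) {
          b <- numeric(P)
        } else {
          mu <- b * (1 - ti) / (1 - t_prev)
          v <- (ti - t_prev) * (1 - ti) / (1 - t_prev)
          b <- mu + stats::rnorm(P, sd = sqrt(max(v, 0)))
        }
        smax <- pmax(smax, abs(gv[i] * b))
        if (refine) {
          dt <- ti - t_prev
          gcell <- max(gv[i - 1L], gv[i])
          cell_hi <- bridge_cell_max(b_prev, b, dt)
          cell_lo <- -bridge_cell_max(-b_prev, -b, dt)
          smax <- pmax(smax, gcell * pmax(cell_hi, -cell_lo))
        }
        t_prev <- ti
      }
      sups <- c(sups, smax)
      remaining <- remaining - P
    }
    bootstrap_quantile(sups, alpha)
  })
}

#' Wild-bootstrap critical value
#'
#' Bootstrap `(1 - alpha)` quantile of the per-draw supremum over
#' `interval` of the transformed replicate process
#' `| What(s) / (1 + sigma^2(s)) * g(sigma^2(s) / (1 + sigma^2(s))) |`,
#' with `sigma^2` supplied through `variance` (typically the empirical
#' wild-bootstrap variance).  With `g = "none"` the transform is the
#' identity, yielding the critical value of the untransformed linear band.
#'
#' @param draws a [wild_bootstrap_paths()] object.
#' @param g weight id: `"g1"`, `"g2"`, or `"none"` for `sup |What|`.
#' @param variance a [step_function()] variance estimate on the jump grid;
#'   defaults to [empirical_variance()] of `draws` (ignored for
#'   `g = "none"`).
#' @param alpha level in (0, 1).
#' @param interval `c(t1, t2)`.
#' @return a single numeric critical value.
#' @export
wb_critical_value <- function(draws, g = c("g2", "g1", "none"),
                              variance = NULL, alpha = 0.05, interval) {
  g <- match.arg(g)
  stopifnot(inherits(draws, "wb_draws"), length(interval) == 2L)
  if (g == "none") {
    return(bootstrap_quantile(sup_statistics(draws, NULL, interval), alpha))
  }
  if (is.null(variance)) variance <- empirical_variance(draws)
  pts <- sup_grid(draws$times, interval)
  s2 <- eval_step(variance, pts)
  phi <- s2 / (1 + s2)
  if (g == "g1" && any(phi < 1e-3 | phi > 1 - 1e-3)) {
    stop("equal-precision weight needs phi in [1e-3, 1 - 1e-3] over the ",
         "interval; the variance is (nearly) zero somewhere - move t1 ",
         "to the right")
  }
  wt <- g_weight(g, phi) / (1 + s2)
  W <- wb_eval_paths(draws, pts)
  sups <- row_max(abs(W * rep(wt, each = nrow(W))))
  bootstrap_quantile(sups, alpha)
}

#' Specification of a time-simultaneous confidence band
#'
#' Five band types are supported, named `<shape>_<calibration>`:
#' `EP` (equal precision, weight `g1`), `HW` (Hall-Wellner, weight `g2`),
#' and `dir` (untransformed linear band); calibration `a` draws critical
#' values from the transformed Brownian bridge, `w` from the wild
#' bootstrap.  The log-transformed EP/HW bands are strictly positive; the
#' linear band `dir_w` may reach below 0.
#'
#' @param band_type one of `"EP_a"`, `"HW_a"`, `"EP_w"`, `"HW_w"`, `"dir_w"`.
#' @param alpha level in (0, 1).
#' @param interval `c(t1, t2)` within `(0, tau]`.
#' @param variance_source `"aalen"`, `"greenwood"` or `"empirical_wb"`;
#'   defaults to `"greenwood"` for Brownian-bridge calibration (more
#'   accurate coverage) and `"empirical_wb"` for wild-bootstrap
#'   calibration.
#' @param multiplier a [multiplier_spec()].
#' @param B number of bootstrap draws.
#' @param bb_paths,bb_grid Monte-Carlo settings for [bb_critical_value()].
#' @return an object of class `"band_spec"`.
#' @export
band_spec <- function(band_type = c("EP_w", "HW_w", "EP_a", "HW_a", "dir_w"),
                      alpha = 0.05, interval, variance_source = NULL,
                      multiplier = multiplier_spec(), B = 1000L,
                      bb_paths = 1000L, bb_grid = 1000L) {
  band_type <- match.arg(band_type)
  stopifnot(alpha > 0, alpha < 1, length(interval) == 2L,
            interval[1] < interval[2])
  if (is.null(variance_source)) {
    variance_source <- if (endsWith(band_type, "_a")) "greenwood"
                       else "empirical_wb"
  }
  variance_source <- match.arg(variance_source,
                               c("aalen", "greenwood", "empirical_wb"))
  structure(
    list(band_type = band_type, alpha = alpha,
         interval = as.numeric(interval),
         variance_source = variance_source, multiplier = multiplier,
         B = as.integer(B), bb_paths = as.integer(bb_paths),
         bb_grid = as.integer(bb_grid)),
    class = "band_spec"
  )
}

# Resolve the variance step function a spec asks for.
resolve_variance <- function(fit, spec, draws = NULL) {
  switch(spec$variance_source,
         aalen = fit$var_aalen,
         greenwood = fit$var_greenwood,
         empirical_wb = {
           if (is.null(draws)) {
             stop("variance_source = 'empirical_wb' needs wild-bootstrap ",
                  "draws")
           }
           empirical_variance(draws)
         })
}

#' Assemble a confidence band from a fit and a critical value
#'
#' Back-transforms a supremum critical value c into the band limits on the
#' jump grid restricted to the interval:
#' EP: `Ahat * exp(-+ c * sigma / (sqrt(n) Ahat))`;
#' HW: `Ahat * exp(-+ c * (1 + sigma^2) / (sqrt(n) Ahat))`;
#' dir: `Ahat -+ c / sqrt(n)`.
#' The log-transformed types require `Ahat(t1) > 0` (the band is unstable
#' near the first event; choose t1 past it).
#'
#' @param fit an [na_fit()].
#' @param critical_value nonnegative supremum quantile.
#' @param spec a [band_spec()].
#' @param variance variance [step_function()] entering the EP/HW formulas;
#'   when `NULL`, resolved from `fit` per `spec$variance_source`
#'   (`empirical_wb` must then be supplied explicitly).
#' @return an object of class `"confidence_band"`.
#' @export
build_band <- function(fit, critical_value, spec, variance = NULL) {
  stopifnot(inherits(fit, "na_fit"), inherits(spec, "band_spec"),
            critical_value >= 0)
  type <- sub("_.*$", "", spec$band_type)
  pts <- sup_grid(fit$estimate$times, spec$interval)
  a <- eval_step(fit$estimate, pts)
  if (type != "dir" && a[1] <= 0) {
    stop("Ahat(t1) = 0: log-transformed bands need at least one event ",
         "before t1; move t1 to the right")
  }
  rn <- sqrt(fit$n)
  if (type != "dir") {
    if (is.null(variance)) variance <- resolve_variance(fit, spec)
    s2 <- eval_step(variance, pts)
  }
  if (type == "EP") {
    half <- critical_value * sqrt(s2) / (rn * a)
    lower <- a * exp(-half); upper <- a * exp(half)
  } else if (type == "HW") {
    half <- critical_value * (1 + s2) / (rn * a)
    lower <- a * exp(-half); upper <- a * exp(half)
  } else {
    lower <- a - critical_value / rn; upper <- a + critical_value / rn
  }
  structure(
    list(times = pts, estimate = a, lower = lower, upper = upper,
         critical_value = critical_value, spec = spec,
         transition = fit$transition, n = fit$n),
    class = "confidence_band"
  )
}

#' One-call confidence band for a cumulative hazard
#'
#' Computes the critical value for the requested band type (Brownian
#' bridge or wild bootstrap) and assembles the band.  For wild-bootstrap
#' types, replicate draws are generated from `fit$cd` unless supplied.
#'
#' Because the supremum statistics are symmetric, the two limits of a
#' band at two-sided level `1 - alpha` also serve as one-sided limits at
#' level at least `1 - alpha` each; [band_limits()] extracts them as step
#' functions for use in the band-inclusion equivalence test.
#'
#' @param fit an [na_fit()].
#' @param spec a [band_spec()].
#' @param draws optional precomputed [wild_bootstrap_paths()] draws.
#' @return a `"confidence_band"` object.
#' @export
na_confidence_band <- function(fit, spec, draws = NULL) {
  stopifnot(inherits(fit, "na_fit"), inherits(spec, "band_spec"))
  type <- sub("_.*$", "", spec$band_type)
  calib <- sub("^.*_", "", spec$band_type)
  g <- switch(type, EP = "g1", HW = "g2", dir = "none")
  if (calib == "a") {
    variance <- resolve_variance(fit, spec)
    phi <- phi_hat(variance)
    plo <- eval_step(phi, spec$interval[1])
    phi_vals <- eval_step(phi, sup_grid(fit$estimate$times, spec$interval))
    phi_hi <- max(phi_vals)
    if (g == "g1" && (plo < 1e-3 || phi_hi > 1 - 1e-3)) {
      stop("equal-precision calibration needs phi(t1) >= 1e-3 and ",
           "phi(t2) <= 1 - 1e-3; move the interval inwards")
    }
    cv <- bb_critical_value(g, plo, phi_hi, spec$alpha,
                            n_paths = spec$bb_paths, grid = spec$bb_grid,
                            seed = derive_seed(spec$multiplier$seed, "bb"))
  } else {
    if (is.null(draws)) {
      draws <- wild_bootstrap_paths(fit$cd, spec$multiplier, spec$B)
    }
    variance <- resolve_variance(fit, spec, draws)
    cv <- wb_critical_value(draws, g, variance, spec$alpha, spec$interval)
  }
  build_band(fit, cv, spec, variance = variance)
}

#' Extract a band's limits as step functions
#'
#' @param band a `"confidence_band"`.
#' @return a list with [step_function()]s `lower` and `upper`.
#' @export
band_limits <- function(band) {
  stopifnot(inherits(band, "confidence_band"))
  list(lower = step_function(band$times, band$lower),
       upper = step_function(band$times, band$upper))
}

#' @export
print.confidence_band <- function(x, ...) {
  cat(sprintf("%s %g%% confidence band on [%g, %g], critical value %.4f\n",
              x$spec$band_type, 100 * (1 - x$spec$alpha),
              x$spec$interval[1], x$spec$interval[2], x$critical_value))
  invisible(x)
}

#' @export
as.data.frame.confidence_band <- function(x, ...) {
  data.frame(time = x$times, estimate = x$estimate, lower = x$lower,
             upper = x$upper)
}

#' Wild-bootstrap confidence band for a within-sample hazard difference
#'
#' For two transitions observed on the *same* sample (shared n), the band
#' `(Ahat_1 - Ahat_2)(s) -+ q / (sqrt(n) g(s))` where q is the bootstrap
#' quantile of `sup |g (What_1 - What_2)|` over the union jump grid in the
#' interval; the replicate draws of the two transitions must be
#' independent.  Default weight `g = 1`.
#'
#' @param fit1,fit2 [na_fit()] objects with equal `n`.
#' @param draws1,draws2 independent [wild_bootstrap_paths()] draws for the
#'   two transitions, same B.
#' @param alpha level.
#' @param interval `c(t1, t2)`.
#' @param g optional positive weight (function, step function or scalar).
#' @return a `"confidence_band"` object for the difference (may be
#'   negative).
#' @export
difference_band <- function(fit1, fit2, draws1, draws2, alpha = 0.05,
                            interval, g = NULL) {
  stopifnot(inherits(fit1, "na_fit"), inherits(fit2, "na_fit"))
  if (fit1$n != fit2$n) {
    stop("difference bands are within-sample: the two fits must share n")
  }
  if (draws1$B != draws2$B) stop("draws must have the same B")
  pts <- sup_grid(sort(unique(c(fit1$estimate$times, fit2$estimate$times))),
                  interval)
  gv <- weight_values(g, pts)
  B <- draws1$B
  D <- (wb_eval_paths(draws1, pts) - wb_eval_paths(draws2, pts)) *
    rep(gv, each = B)
  q <- bootstrap_quantile(row_max(abs(D)), alpha)
  diff <- eval_step(fit1$estimate, pts) - eval_step(fit2$estimate, pts)
  half <- q / (sqrt(fit1$n) * gv)
  spec <- band_spec("dir_w", alpha, interval, multiplier = draws1$multiplier,
                    B = B)
  spec$band_type <- "diff_w"
  structure(
    list(times = pts, estimate = diff, lower = diff - half,
         upper = diff + half, critical_value = q, spec = spec,
         transition = c(fit1$transition, fit2$transition), n = fit1$n),
    class = "confidence_band"
  )
}

#' Simultaneous confidence intervals over a finite set of time points
#'
#' Replaces the supremum in the wild-bootstrap critical value with the
#' maximum over the given time points, then applies the band formulas at
#' each point.  With a single time point this reduces to the pointwise
#' bootstrap interval.
#'
#' @param fit an [na_fit()].
#' @param draws [wild_bootstrap_paths()] draws for the transition.
#' @param timepoints finite nonempty set of times in `(0, tau]`.
#' @param alpha level.
#' @param band_type `"dir_w"`, `"EP_w"` or `"HW_w"`.
#' @param variance variance [step_function()] for the transformed types;
#'   defaults to the empirical wild-bootstrap variance.
#' @return a `data.frame` with columns `time, estimate, lower, upper`;
#'   the shared critical value is in attribute `"critical_value"`.
#' @export
simultaneous_intervals <- function(fit, draws, timepoints, alpha = 0.05,
                                   band_type = c("dir_w", "EP_w", "HW_w"),
                                   variance = NULL) {
  band_type <- match.arg(band_type)
  if (length(timepoints) == 0L) stop("at least one time point is required")
  stopifnot(all(timepoints > 0), all(timepoints <= fit$tau))
  pts <- sort(unique(timepoints))
  type <- sub("_.*$", "", band_type)
  B <- draws$B
  W <- wb_eval_paths(draws, pts)
  a <- eval_step(fit$estimate, pts)
  if (type == "dir") {
    cv <- bootstrap_quantile(row_max(abs(W)), alpha)
    lower <- a - cv / sqrt(fit$n); upper <- a + cv / sqrt(fit$n)
  } else {
    if (is.null(variance)) variance <- empirical_variance(draws)
    if (any(a <= 0)) {
      stop("log-transformed intervals need Ahat > 0 at every time point")
    }
    s2 <- eval_step(variance, pts)
    phi <- s2 / (1 + s2)
    g <- if (type == "EP") "g1" else "g2"
    if (g == "g1" && any(phi < 1e-3 | phi > 1 - 1e-3)) {
      stop("equal-precision weight needs phi in [1e-3, 1 - 1e-3] at every ",
           "time point")
    }
    wt <- g_weight(g, phi) / (1 + s2)
    cv <- bootstrap_quantile(row_max(abs(W * rep(wt, each = B))), alpha)
    half <- if (type == "EP") cv * sqrt(s2) / (sqrt(fit$n) * a)
            else cv * (1 + s2) / (sqrt(fit$n) * a)
    lower <- a * exp(-half); upper <- a * exp(half)
  }
  out <- data.frame(time = pts, estimate = a, lower = lower, upper = upper)
  attr(out, "critical_value") <- cv
  attr(out, "alpha") <- alpha
  out
}

#' Sidak-corrected joint confidence region across transitions
#'
#' Pointwise intervals for k asymptotically independent cumulative hazards
#' at a common time, each at level `(1 - alpha)^(1/k)`, so that the
#' product region has asymptotic joint coverage `1 - alpha`.
#'
#' @param fits list of k [na_fit()] objects.
#' @param draws_list list of k matching [wild_bootstrap_paths()] draws.
#' @param t single time point.
#' @param alpha joint level.
#' @param band_type interval shape, as in [simultaneous_intervals()].
#' @return a `data.frame` with one row per transition.
#' @export
sidak_region <- function(fits, draws_list, t, alpha = 0.05,
                         band_type = "dir_w") {
  k <- length(fits)
  stopifnot(k >= 1, length(draws_list) == k, length(t) == 1L)
  alpha_each <- 1 - (1 - alpha)^(1 / k)
  rows <- lapply(seq_len(k), function(i) {
    ci <- simultaneous_intervals(fits[[i]], draws_list[[i]], t, alpha_each,
                                 band_type)
    data.frame(from = fits[[i]]$transition[["from"]],
               to = fits[[i]]$transition[["to"]],
               time = ci$time, estimate = ci$estimate, lower = ci$lower,
               upper = ci$upper, level_each = 1 - alpha_each,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a confidence band as delimited text with a metadata header
#'
#' `#`-prefixed header lines record band type, level, critical value, B and
#' seed, followed by `time,estimate,lower,upper` rows.
#'
#' @param band a `"confidence_band"`.
#' @param path file path.
#' @export
write_band <- function(band, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sp <- band$spec
  writeLines(c(
    sprintf("# band_type: %s", sp$band_type),
    sprintf("# alpha: %g", sp$alpha),
    sprintf("# interval: %g %g", sp$interval[1], sp$interval[2]),
    sprintf("# critical_value: %.10g", band$critical_value),
    sprintf("# B: %d", sp$B),
    sprintf("# multiplier: %s", sp$multiplier$family),
    sprintf("# seed: %d", sp$multiplier$seed),
    sprintf("# n: %d", band$n)
  ), con)
  utils::write.table(as.data.frame(band), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
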