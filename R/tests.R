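new_test_result <- function(test, statistic, critical_value, p_value, reject,
                            alpha, B, interval, multiplier = NA_character_,
                            seed = NA_integer_) {
  structure(
    list(test = test, statistic = statistic, critical_value = critical_value,
         p_value = p_value, reject = reject, alpha = alpha, B = B,
         interval = interval, multiplier = multiplier, seed = seed),
    class = "na_test"
  )
}

#' @export
print.na_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4f, critical value = %.4f", x$test,
              x$statistic, x$critical_value))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4f", x$p_value))
  cat(sprintf("\n  reject at level %g: %s\n", x$alpha,
              if (isTRUE(x$reject)) "yes" else "no"))
  invisible(x)
}

# Add-one bootstrap p-value: never exactly zero.
boot_p_value <- function(sups, statistic) {
  (1 + sum(sups >= statistic)) / (length(sups) + 1)
}

#' Kolmogorov-Smirnov test for equality of two cumulative hazards
#'
#' Within-sample comparison of two transitions observed on the same n
#' subjects (e.g. two competing risks): tests `A_1 = A_2` on the interval
#' against a two-sided alternative.  The statistic is
#' `sup sqrt(n) g |Ahat_1 - Ahat_2|` over the union jump grid; the critical
#' value is the bootstrap quantile of `sup |g (What_1 - What_2)|`, using
#' independent multiplier streams for the two transitions.  The p-value
#' uses the add-one rule `(1 + #{draws >= stat}) / (B + 1)`.
#'
#' @param fit1,fit2 [na_fit()] objects sharing `n`.
#' @param draws1,draws2 independent [wild_bootstrap_paths()] draws.
#' @param g optional positive weight.
#' @param alpha level.
#' @param interval `c(t1, t2)`.
#' @return an object of class `"na_test"`.
#' @export
ks_equality_test <- function(fit1, fit2, draws1, draws2, g = NULL,
                             alpha = 0.05, interval) {
  stopifnot(inherits(fit1, "na_fit"), inherits(fit2, "na_fit"))
  if (fit1$n != fit2$n) {
    stop("the equality test compares transitions within one sample: ",
         "the fits must share n")
  }
  if (draws1$B != draws2$B) stop("draws must have the same B")
  pts <- sup_grid(sort(unique(c(fit1$estimate$times, fit2$estimate$times))),
                  interval)
  gv <- weight_values(g, pts)
  stat <- max(sqrt(fit1$n) * gv *
                abs(eval_step(fit1$estimate, pts) -
                      eval_step(fit2$estimate, pts)))
  B <- draws1$B
  D <- (wb_eval_paths(draws1, pts) - wb_eval_paths(draws2, pts)) *
    rep(gv, each = B)
  sups <- row_max(abs(D))
  crit <- bootstrap_quantile(sups, alpha)
  new_test_result("KS equality test (within sample)", stat, crit,
                  boot_p_value(sups, stat), stat > crit, alpha, B, interval,
                  draws1$multiplier$family, draws1$multiplier$seed)
}

#' Equivalence margins around a reference cumulative hazard
#'
#' @param A0 reference cumulative hazard: a [step_function()] or a
#'   nondecreasing function of time.
#' @param ell,u strictly positive lower/upper margins: constants or
#'   functions of time.
#' @return an object of class `"equivalence_margins"`.
#' @export
equivalence_margins <- function(A0, ell, u) {
  chk <- function(m, nm) {
    if (is.numeric(m) && length(m) == 1L) {
      if (m <= 0) stop("margin `", nm, "` must be strictly positive")
    } else if (!is.function(m)) {
      stop("margin `", nm, "` must be a positive constant or function")
    }
    m
  }
  structure(list(A0 = A0, ell = chk(ell, "ell"), u = chk(u, "u")),
            class = "equivalence_margins")
}

eval_margin <- function(m, pts) {
  if (is.function(m)) {
    v <- m(pts)
  } else if (inherits(m, "step_function")) {
    v <- eval_step(m, pts)
  } else {
    v <- rep(m, length(pts))
  }
  v
}

#' Equivalence test by confidence-band inclusion
#'
#' Tests non-equivalence `H: A <= A0 - ell or A >= A0 + u somewhere` against
#' equivalence `K: A0 - ell < A < A0 + u everywhere on the interval`.
#' H is rejected iff the combined band `(a_n, b_n)` lies *strictly* inside
#' the open margin region at every checked time; a band limit touching a
#' margin does not reject.  The two one-sided limits are taken at level
#' `1 - alpha` each (intersection-union logic), so the test has asymptotic
#' level alpha.
#'
#' The reported statistic is the maximal margin violation
#' `max( (A0 - ell) - a_n, b_n - (A0 + u) )`; rejection corresponds to a
#' strictly negative statistic (critical value 0).
#'
#' @param one_sided_lower,one_sided_upper lower/upper band limits `a_n`,
#'   `b_n` as [step_function()]s, each at one-sided level `1 - alpha`.
#' @param margins an [equivalence_margins()] object.
#' @param interval `c(t1, t2)`.
#' @param grid_points number of extra check points for continuous margins
#'   (all step-function knots are always included).
#' @return an object of class `"na_test"` (`p_value` is `NA`: the decision
#'   comes from band inclusion, not a resampled statistic).
#' @export
equivalence_test <- function(one_sided_lower, one_sided_upper, margins,
                             interval, grid_points = 201L) {
  stopifnot(inherits(margins, "equivalence_margins"),
            inherits(one_sided_lower, "step_function"),
            inherits(one_sided_upper, "step_function"))
  t1 <- interval[1]; t2 <- interval[2]
  knots <- c(one_sided_lower$times, one_sided_upper$times)
  if (inherits(margins$A0, "step_function")) {
    knots <- c(knots, margins$A0$times)
  }
  pts <- sort(unique(c(t1, t2, knots[knots > t1 & knots < t2],
                       seq(t1, t2, length.out = grid_points))))
  a <- eval_step(one_sided_lower, pts)
  b <- eval_step(one_sided_upper, pts)
  A0 <- eval_margin(margins$A0, pts)
  ell <- eval_margin(margins$ell, pts)
  u <- eval_margin(margins$u, pts)
  if (any(ell <= 0) || any(u <= 0)) {
    stop("equivalence margins must be strictly positive on the interval")
  }
  violation <- pmax((A0 - ell) - a, b - (A0 + u))
  stat <- max(violation)
  new_test_result("equivalence test by band inclusion", stat, 0, NA_real_,
                  stat < 0, NA_real_, NA_integer_, interval)
}

#' Two-sample wild-bootstrap test for proportional hazards
#'
#' Tests `H0: alpha^(1) = c * alpha^(2) on [0, tau] for some c > 0`
#' (equivalently `A^(1) = c A^(2)`) for two independent samples.  The
#' statistic compares the ratio process against its value at tau:
#' `T = rho( sqrt(n1 n2 / n) Ahat2 / Ahat1,
#'           sqrt(n1 n2 / n) Ahat2(tau) / Ahat1(tau) )`
#' with weight `w = Ahat1`, which confines the evaluation to
#' `{Ahat1 > 0}`.  `rho` is the weighted Kolmogorov-Smirnov sup-distance or
#' the Cramer-von-Mises integral `int (f - g)^2 w^2 dlambda` on `[0, tau]`,
#' computed exactly as a sum over the piecewise-constant segments between
#' pooled jump times.  The critical value is the bootstrap quantile of the
#' same functional applied to the delta-method replicate process
#' `sqrt(n1/n) What2 / Ahat1 - sqrt(n2/n) What1 Ahat2 / Ahat1^2` centered
#' at its value at tau.
#'
#' @param cd1,cd2 [build_counting_data()] objects for the same transition
#'   in two independent samples (sizes `n1`, `n2`).
#' @param rho `"KS"` or `"CvM"`.
#' @param alpha level.
#' @param B number of bootstrap draws.
#' @param tau right end of the domain of interest; defaults to the smaller
#'   of the two horizons.
#' @param spec a [multiplier_spec()]; the two samples get independent
#'   streams derived from its seed.
#' @return an object of class `"na_test"`.
#' @export
proportionality_test <- function(cd1, cd2, rho = c("KS", "CvM"),
                                 alpha = 0.05, B = 1000L, tau = NULL,
                                 spec = multiplier_spec()) {
  rho <- match.arg(rho)
  stopifnot(inherits(cd1, "counting_data"), inherits(cd2, "counting_data"))
  if (is.null(tau)) tau <- min(cd1$tau, cd2$tau)
  n1 <- cd1$n; n2 <- cd2$n; n <- n1 + n2
  A1 <- nelson_aalen(cd1); A2 <- nelson_aalen(cd2)
  grid <- sort(unique(c(cd1$times, cd2$times)))
  grid <- grid[grid <= tau]
  a1 <- eval_step(A1, grid)
  keep <- a1 > 0
  grid <- grid[keep]; a1 <- a1[keep]
  if (length(grid) == 0L) {
    stop("Ahat^(1) is identically zero on (0, tau]: the weighted ",
         "proportionality statistic is undefined")
  }
  a2 <- eval_step(A2, grid)
  a1tau <- eval_step(A1, tau); a2tau <- eval_step(A2, tau)
  rt <- sqrt(n1 * n2 / n)
  fdev <- rt * (a2 / a1 - a2tau / a1tau)     # f - f(tau), pre-weighting
  w <- a1
  seg_len <- c(grid[-1L], tau) - grid        # CvM segment lengths to tau
  stat <- if (rho == "KS") max(abs(fdev) * w)
          else sum((fdev * w)^2 * seg_len)

  draws1 <- wild_bootstrap_paths(cd1, spec, B, stream = 1L)
  draws2 <- wild_bootstrap_paths(cd2, spec, B, stream = 2L)
  W1 <- wb_eval_paths(draws1, grid); W2 <- wb_eval_paths(draws2, grid)
  c1 <- sqrt(n1 / n); c2 <- sqrt(n2 / n)
  D <- W2 * rep(c1 / a1, each = B) - W1 * rep(c2 * a2 / a1^2, each = B)
  W1tau <- drop(wb_eval_paths(draws1, tau))
  W2tau <- drop(wb_eval_paths(draws2, tau))
  Dtau <- c1 * W2tau / a1tau - c2 * W1tau * a2tau / a1tau^2
  Ddev <- D - Dtau                           # recycles Dtau down columns
  sups <- if (rho == "KS") {
    row_max(abs(Ddev) * rep(w, each = B))
  } else {
    drop((Ddev * rep(w, each = B))^2 %*% seg_len)
  }
  crit <- bootstrap_quantile(sups, alpha)
  new_test_result(sprintf("two-sample proportional hazards test (%s)", rho),
                  stat, crit, boot_p_value(sups, stat), stat > crit, alpha,
                  B, c(0, tau), spec$family, spec$seed)
}

#' Two-sample Kolmogorov-Smirnov test for equality of cumulative hazards
#'
#' Unpaired two-sample analogue of [ks_equality_test()]: tests
#' `A^(1) = A^(2)` on the interval with statistic
#' `sqrt(n1 n2 / n) sup g |Ahat1 - Ahat2|` and bootstrap process
#' `sqrt(n1/n) What2 - sqrt(n2/n) What1` (whose distribution is symmetric
#' in the sample labels).
#'
#' @inheritParams proportionality_test
#' @param g optional positive weight.
#' @param interval `c(t1, t2)`; defaults to `c(0, min(tau1, tau2))`.
#' @return an object of class `"na_test"`.
#' @export
ks_two_sample_equality_test <- function(cd1, cd2, g = NULL, alpha = 0.05,
                                        B = 1000L, interval = NULL,
                                        spec = multiplier_spec()) {
  stopifnot(inherits(cd1, "counting_data"), inherits(cd2, "counting_data"))
  if (is.null(interval)) interval <- c(0, min(cd1$tau, cd2$tau))
  n1 <- cd1$n; n2 <- cd2$n; n <- n1 + n2
  A1 <- nelson_aalen(cd1); A2 <- nelson_aalen(cd2)
  pts <- sup_grid(sort(unique(c(cd1$times, cd2$times))), interval)
  gv <- weight_values(g, pts)
  rt <- sqrt(n1 * n2 / n)
  stat <- max(rt * gv * abs(eval_step(A1, pts) - eval_step(A2, pts)))
  draws1 <- wild_bootstrap_paths(cd1, spec, B, stream = 1L)
  draws2 <- wild_bootstrap_paths(cd2, spec, B, stream = 2L)
  D <- (sqrt(n1 / n) * wb_eval_paths(draws2, pts) -
          sqrt(n2 / n) * wb_eval_paths(draws1, pts)) * rep(gv, each = B)
  sups <- row_max(abs(D))
  crit <- bootstrap_quantile(sups, alpha)
  new_test_result("KS equality test (two samples)", stat, crit,
                  boot_p_value(sups, stat), stat > crit, alpha, B, interval,
                  spec$family, spec$seed)
}

#' Write a test result as a JSON-lines record
#'
#' @param x an `"na_test"` result.
#' @param path file path or `""` for standard output.
#' @export
write_test_result <- function(x, path = "") {
  stopifnot(inherits(x, "na_test"))
  rec <- list(test = x$test, statistic = x$statistic,
              critical_value = x$critical_value, p_value = x$p_value,
              reject = x$reject, alpha = x$alpha, B = x$B,
              interval = x$interval, multiplier = x$multiplier,
              seed = x$seed)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                           na = "null")
  if (identical(path, "")) cat(line, "\n", sep = "") else
    writeLines(as.character(line), path)
  invisible(x)
}
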