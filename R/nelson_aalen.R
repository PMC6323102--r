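#' Nelson-Aalen estimator of a cumulative transition hazard
#'
#' The canonical nonparametric estimate of the cumulative hazard
#' A(t) = int_0^t alpha(s) ds under the multiplicative intensity model
#' lambda(t) = alpha(t) Y(t): a cumulative sum of dN(s)/Y(s) over the
#' observed jump times s <= t (with the 0/0 := 0 convention handled by the
#' jump grid, on which Y > 0 always).
#'
#' @param cd a [build_counting_data()] object.
#' @return a [step_function()] for the estimate.
#' @export
nelson_aalen <- function(cd) {
  stopifnot(inherits(cd, "counting_data"))
  step_function(cd$times, cumsum(cd$delta_n / cd$y))
}

#' Aalen-type variance estimator
#'
#' The optional-variation-based estimator
#' `sigma^2(t) = n * sum_{s <= t} dN(s) / Y(s)^2` of the asymptotic variance
#' of the normalized Nelson-Aalen process `sqrt(n) (Ahat - A)`.
#'
#' @inheritParams nelson_aalen
#' @return a [step_function()].
#' @export
aalen_variance <- function(cd) {
  stopifnot(inherits(cd, "counting_data"))
  step_function(cd$times, cd$n * cumsum(cd$delta_n / cd$y^2))
}

#' Greenwood-type variance estimator
#'
#' `sigma^2(t) = n * sum_{s <= t} (Y(s) - dN(s)) dN(s) / Y(s)^3`; never
#' exceeds the Aalen-type estimator and vanishes when the last subject at
#' risk has the event.
#'
#' @inheritParams nelson_aalen
#' @return a [step_function()].
#' @export
greenwood_variance <- function(cd) {
  stopifnot(inherits(cd, "counting_data"))
  step_function(cd$times,
                cd$n * cumsum((cd$y - cd$delta_n) * cd$delta_n / cd$y^3))
}

#' Fit the Nelson-Aalen estimator together with both variance estimators
#'
#' Convenience container bundling the estimate and the Aalen- and
#' Greenwood-type variance estimators on the shared jump grid of the
#' counting data; all downstream band and test machinery consumes it.
#'
#' @inheritParams nelson_aalen
#' @return an object of class `"na_fit"` with fields `transition`,
#'   `estimate`, `var_aalen`, `var_greenwood`, `n`, `tau`, `n_events`, `cd`.
#' @examples
#' rec <- event_records(c("a", "b", "c"), 0, c(1, 2, 2.5), "0",
#'                      c("2", "2", "cens"))
#' fit <- na_fit(build_counting_data(rec, "0", "2", tau = 3))
#' eval_step(fit$estimate, 2)        # 1/3 + 1/2
#' eval_step(fit$var_aalen, 2)       # 3 * (1/9 + 1/4)
#' @export
na_fit <- function(cd) {
  stopifnot(inherits(cd, "counting_data"))
  structure(
    list(transition = cd$transition,
         estimate = nelson_aalen(cd),
         var_aalen = aalen_variance(cd),
         var_greenwood = greenwood_variance(cd),
         n = cd$n, tau = cd$tau, n_events = sum(cd$delta_n), cd = cd),
    class = "na_fit"
  )
}

#' @export
print.na_fit <- function(x, ...) {
  cat(sprintf("Nelson-Aalen fit %s -> %s (n = %d, %d events, tau = %g)\n",
              x$transition["from"], x$transition["to"], x$n, x$n_events,
              x$tau))
  if (length(x$estimate$times)) {
    tl <- max(x$estimate$times)
    cat(sprintf("  A(%g) = %.4f  [var Aalen %.4f, Greenwood %.4f]\n",
                tl, eval_step(x$estimate, tl), eval_step(x$var_aalen, tl),
                eval_step(x$var_greenwood, tl)))
  }
  invisible(x)
}

#' Export a step function as two-column delimited text
#'
#' Writes `time,value` rows with an explicit `(0, 0)` first row, the
#' file-level analogue of the zero-at-zero convention.
#'
#' @param f a [step_function()].
#' @param path file path.
#' @param sep field separator.
#' @export
write_step_function <- function(f, path, sep = ",") {
  utils::write.table(as.data.frame(f), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_step_function
#' @export
read_step_function <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  df <- df[df$time > 0, , drop = FALSE]
  step_function(df$time, df$value)
}
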