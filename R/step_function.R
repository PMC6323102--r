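#' Right-continuous step functions anchored at zero
#'
#' The carrier type for all estimated processes in the package: the
#' Nelson-Aalen estimate, its variance estimators, the wild-bootstrap
#' variance and band limits are all cadlag piecewise-constant functions with
#' value 0 at time 0.  `step_function(times, values)` stores the jump grid
#' and the function values *at* the jump times; evaluation is
#' right-continuous, i.e. `f(t)` is the value at the largest stored time
#' `<= t`, 0 before the first jump, and constant beyond the last jump.
#'
#' @param times strictly increasing positive jump times (possibly empty).
#' @param values function values at `times`, same length.
#' @return an object of class `"step_function"`.
#' @examples
#' f <- step_function(c(1, 2), c(1 / 3, 5 / 6))
#' eval_step(f, c(0, 0.5, 1, 1.5, 2, 10))
#' @export
step_function <- function(times = numeric(0), values = numeric(0)) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length")
  }
  if (length(times) > 0L) {
    if (any(times <= 0)) stop("step-function times must be positive")
    if (is.unsorted(times, strictly = TRUE)) {
      stop("step-function times must be strictly increasing")
    }
  }
  structure(list(times = times, values = values), class = "step_function")
}

#' Evaluate a step function
#'
#' @param f a [step_function()].
#' @param t numeric vector of evaluation times.
#' @return numeric vector `f(t)`.
#' @export
eval_step <- function(f, t) {
  stopifnot(inherits(f, "step_function"))
  idx <- findInterval(t, f$times)
  out <- numeric(length(t))
  pos <- idx > 0L
  out[pos] <- f$values[idx[pos]]
  out
}

#' @export
print.step_function <- function(x, ...) {
  cat("step function with", length(x$times), "jump times")
  if (length(x$times)) {
    cat(" on (0,", format(max(x$times)), "], last value ",
        format(x$values[length(x$values)]), sep = "")
  } else {
    cat(" (identically zero)")
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.step_function <- function(x, ...) {
  data.frame(time = c(0, x$times), value = c(0, x$values))
}

# Jump times of f lying in (t1, t2], prepended with t1 itself: the exact
# evaluation grid for suprema of processes that are constant between jumps.
sup_grid <- function(times, interval) {
  t1 <- interval[1]
  t2 <- interval[2]
  if (t1 > t2) stop("empty interval: t1 > t2")
  c(t1, times[times > t1 & times <= t2])
}
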