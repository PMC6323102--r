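#' Multiplier family specification for the wild bootstrap
#'
#' White-noise multipliers must have mean 0 and variance 1.  Two families
#' are provided: standard normal and centered Poisson(1) (i.e. a Poisson(1)
#' variate minus 1, which has skewness one and can improve small-sample
#' behaviour).  The seed is the root of the deterministic stream-derivation
#' scheme (see [derive_seed()]): every transition and bootstrap stream gets
#' its own reproducible sub-stream.
#'
#' @param family `"standard_normal"` or `"centered_poisson1"` (aliases
#'   `"normal"`, `"poisson"` accepted).
#' @param seed integer root seed.
#' @return an object of class `"multiplier_spec"`.
#' @export
multiplier_spec <- function(family = c("standard_normal", "centered_poisson1",
                                       "normal", "poisson"),
                            seed = 1L) {
  family <- match.arg(family)
  family <- switch(family, normal = "standard_normal",
                   poisson = "centered_poisson1", family)
  structure(list(family = family, seed = as.integer(seed)),
            class = "multiplier_spec")
}

# i.i.d. multiplier draws using the *current* RNG state.
rmultiplier <- function(family, m) {
  switch(family,
         standard_normal = stats::rnorm(m),
         centered_poisson1 = stats::rpois(m, 1) - 1,
         stop("unknown multiplier family: ", family))
}

#' Draw a table of i.i.d. wild-bootstrap multipliers
#'
#' @param spec a [multiplier_spec()].
#' @param num_events number of unit event increments (columns).
#' @param B number of bootstrap draws (rows).
#' @return a `B x num_events` matrix, reproducible under a fixed seed.
#' @export
draw_multipliers <- function(spec, num_events, B) {
  stopifnot(inherits(spec, "multiplier_spec"), num_events >= 0, B >= 1)
  with_seed(spec$seed,
            matrix(rmultiplier(spec$family, B * num_events), nrow = B))
}

#' Wild-bootstrap replicate paths of the normalized Nelson-Aalen process
#'
#' Generates B replicates of the resampled process
#' `What(t) = sqrt(n) * sum_{events e <= t} G_e / Y(e)`, obtained from the
#' martingale representation of the Nelson-Aalen estimator by substituting
#' the unobservable martingale increments with multiplier-weighted observed
#' increments.  One independent multiplier is attached to every *unit*
#' event: a tied jump of size dN consumes dN i.i.d. multipliers.  Per draw,
#' the bootstrap (optional-variation) variance process
#' `sigma*^2(t) = n * sum_{e <= t} G_e^2 / Y(e)^2` is stored alongside.
#'
#' Only multiplier values at event times are materialized; the white-noise
#' process is never simulated on a continuum, because the bootstrap
#' integral only sees the jump times of N.
#'
#' @param cd a [build_counting_data()] object.
#' @param spec a [multiplier_spec()]; the actual stream seed is derived from
#'   `spec$seed`, the transition labels and `stream`.
#' @param B number of bootstrap draws, `>= 1`.
#' @param stream integer tag separating independent streams that share a
#'   root seed (e.g. the two samples of a two-sample test).
#' @param multipliers optional `B x num_events` matrix overriding the random
#'   multipliers (used for exact checks; bypasses the RNG entirely).
#' @return an object of class `"wb_draws"`: fields `transition`, `times`,
#'   `paths` (`B x` #jump times), `star_var` (same shape), `n`, `B`,
#'   `multiplier`, `stream`.
#' @export
wild_bootstrap_paths <- function(cd, spec = multiplier_spec(), B = 1000L,
                                 stream = 0L, multipliers = NULL) {
  stopifnot(inherits(cd, "counting_data"))
  if (B < 1) stop("B must be at least 1")
  E <- sum(cd$delta_n)
  if (is.null(multipliers)) {
    seed <- derive_seed(spec$seed, stream, cd$transition[["from"]],
                        cd$transition[["to"]])
    G <- with_seed(seed, matrix(rmultiplier(spec$family, B * E), nrow = B))
  } else {
    G <- as.matrix(multipliers)
    if (nrow(G) != B || ncol(G) != E) {
      stop("`multipliers` must be a B x (number of unit events) matrix")
    }
  }
  if (E == 0L) {
    paths <- matrix(numeric(0), nrow = B, ncol = 0)
    star_var <- paths
  } else {
    w <- rep(1 / cd$y, cd$delta_n)            # 1/Y per unit event
    last <- cumsum(cd$delta_n)                # last unit event of each tie
    paths <- sqrt(cd$n) *
      row_cumsum(G * rep(w, each = B))[, last, drop = FALSE]
    star_var <- cd$n *
      row_cumsum(G^2 * rep(w^2, each = B))[, last, drop = FALSE]
  }
  structure(
    list(transition = cd$transition, times = cd$times, paths = paths,
         star_var = star_var, n = cd$n, B = as.integer(B),
         multiplier = spec, stream = as.integer(stream)),
    class = "wb_draws"
  )
}

#' @export
print.wb_draws <- function(x, ...) {
  cat(sprintf("wild bootstrap draws %s -> %s: B = %d, %d jump times, %s multipliers\n",
              x$transition["from"], x$transition["to"], x$B,
              length(x$times), x$multiplier$family))
  invisible(x)
}

#' Evaluate wild-bootstrap replicate paths at arbitrary times
#'
#' Paths start at 0 and are constant between jump times.
#'
#' @param draws a [wild_bootstrap_paths()] object.
#' @param times numeric vector of evaluation times.
#' @param what evaluate the paths or the per-draw variance processes.
#' @return a `B x length(times)` matrix.
#' @export
wb_eval_paths <- function(draws, times, what = c("paths", "star_var")) {
  what <- match.arg(what)
  m <- draws[[what]]
  idx <- findInterval(times, draws$times)
  out <- matrix(0, nrow = nrow(m), ncol = length(times))
  pos <- idx > 0L
  if (any(pos)) out[, pos] <- m[, idx[pos], drop = FALSE]
  out
}

#' Empirical variance of the wild-bootstrap replicates
#'
#' At each jump time, the mean across draws of the squared path values.
#' The uncentered second moment is used by default because the conditional
#' mean of the bootstrap process given the data is exactly 0 by
#' construction; set `center = TRUE` for the centered version.
#'
#' @param draws a [wild_bootstrap_paths()] object with `B >= 2`.
#' @param center center at the across-draw mean first?
#' @return a [step_function()] on the jump grid.
#' @export
empirical_variance <- function(draws, center = FALSE) {
  stopifnot(inherits(draws, "wb_draws"))
  if (draws$B < 2) stop("empirical variance requires B >= 2")
  p <- draws$paths
  if (center) p <- sweep(p, 2L, colMeans(p))
  step_function(draws$times, colMeans(p^2))
}

#' Per-draw supremum statistics
#'
#' For each bootstrap replicate, the supremum over the jump times inside
#' `interval` of `|weight(s) * What(s)|`.  Because all paths are constant
#' between jumps, the supremum is evaluated exactly on the jump grid
#' (plus the left endpoint); over an empty grid it is 0.
#'
#' @param draws a [wild_bootstrap_paths()] object.
#' @param weight `NULL` (weight 1), a function of time, or a
#'   [step_function()].
#' @param interval `c(t1, t2)` with `t1 <= t2`.
#' @return numeric vector of length B.
#' @export
sup_statistics <- function(draws, weight = NULL, interval) {
  stopifnot(inherits(draws, "wb_draws"), length(interval) == 2L)
  pts <- sup_grid(draws$times, interval)
  W <- wb_eval_paths(draws, pts)
  wt <- weight_values(weight, pts)
  row_max(abs(W * rep(wt, each = nrow(W))))
}

# Resolve a weight argument (NULL / function / step_function) on a grid.
weight_values <- function(weight, pts) {
  if (is.null(weight)) return(rep(1, length(pts)))
  if (inherits(weight, "step_function")) return(eval_step(weight, pts))
  if (is.function(weight)) return(weight(pts))
  if (is.numeric(weight) && length(weight) == 1L) {
    return(rep(weight, length(pts)))
  }
  stop("`weight` must be NULL, a function, a step_function or a scalar")
}

#' Upper-quantile rule for bootstrap critical values
#'
#' The ceiling((1 - alpha) * B)-th order statistic of the B resampled
#' statistics: a conservative, distribution-free quantile rule.
#'
#' @param values numeric vector of resampled statistics, non-empty.
#' @param alpha level in (0, 1).
#' @return a single numeric critical value.
#' @export
bootstrap_quantile <- function(values, alpha) {
  if (length(values) == 0L) stop("no bootstrap values supplied")
  stopifnot(alpha > 0, alpha < 1)
  sort(values)[ceiling((1 - alpha) * length(values))]
}

#' Export wild-bootstrap paths as delimited text
#'
#' Rows are draws, columns are jump times; the header row carries the times.
#'
#' @param draws a [wild_bootstrap_paths()] object.
#' @param path file path.
#' @param sep field separator.
#' @export
write_wb_draws <- function(draws, path, sep = ",") {
  m <- draws$paths
  colnames(m) <- format(draws$times, digits = 12, trim = TRUE)
  utils::write.table(m, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
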