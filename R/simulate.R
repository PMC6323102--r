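#' Administrative censoring time achieving a target censored fraction
#'
#' Under a constant all-cause hazard, administrative censoring at time c
#' leaves a subject censored with probability `exp(-hazard * c)`; solving
#' for the target fraction gives `c = -log(fraction) / total_hazard`.
#'
#' @param total_hazard positive all-cause hazard.
#' @param fraction target censored fraction in (0, 1).
#' @return the censoring time c.
#' @examples
#' censoring_time_for_fraction(4, 0.25)  # log(4) / 4
#' @export
censoring_time_for_fraction <- function(total_hazard, fraction) {
  stopifnot(total_hazard > 0)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1")
  }
  -log(fraction) / total_hazard
}

#' Two-group constant-hazard competing-risks scenario
#'
#' The four study scenarios vary the type-1 (0 -> 1) hazard across two
#' unpaired groups while keeping the competing (0 -> 2) hazard at 2 in
#' both; all hazards are constant in time, so the type-1 hazards of the
#' two groups are always proportional (null scenarios for the
#' proportionality test):
#' \describe{
#'   \item{I}{type-1 hazard 2 in both groups (ratio 1),}
#'   \item{II}{1 vs 2 (large effect),}
#'   \item{III}{1 in both groups,}
#'   \item{IV}{1 vs 1.5 (moderate effect).}
#' }
#' Each group is administratively censored at the time that leaves
#' approximately `censoring_fraction` of its subjects censored
#' (see [censoring_time_for_fraction()]; the fraction is per group).
#'
#' @param scenario `"I"`, `"II"`, `"III"`, `"IV"`, or `NULL` to pass
#'   explicit hazards.
#' @param hazards_group1,hazards_group2 `c(alpha01, alpha02)` per group
#'   (ignored when `scenario` is given).
#' @param n_per_group subjects per group.
#' @param tau right end of the domain of interest.
#' @param censoring_fraction target censored fraction per group.
#' @param seed RNG seed.
#' @return an object of class `"cr_scenario"`.
#' @export
competing_risks_scenario <- function(scenario = NULL,
                                     hazards_group1 = NULL,
                                     hazards_group2 = NULL,
                                     n_per_group = 125L, tau = 0.3,
                                     censoring_fraction = 0.25, seed = 1L) {
  presets <- list(I = list(c(2, 2), c(2, 2)),
                  II = list(c(1, 2), c(2, 2)),
                  III = list(c(1, 2), c(1, 2)),
                  IV = list(c(1, 2), c(1.5, 2)))
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, names(presets))
    hazards_group1 <- presets[[scenario]][[1]]
    hazards_group2 <- presets[[scenario]][[2]]
  } else {
    scenario <- "custom"
  }
  stopifnot(length(hazards_group1) == 2L, length(hazards_group2) == 2L,
            all(hazards_group1 > 0), all(hazards_group2 > 0),
            n_per_group >= 1, tau > 0)
  structure(
    list(scenario = scenario,
         hazards_group1 = as.numeric(hazards_group1),
         hazards_group2 = as.numeric(hazards_group2),
         n_per_group = as.integer(n_per_group), tau = tau,
         censoring_fraction = censoring_fraction,
         seed = as.integer(seed)),
    class = "cr_scenario"
  )
}

#' Simulate event histories from a two-group competing-risks scenario
#'
#' Per subject: latent event time Exponential(alpha01 + alpha02), cause 1
#' with probability alpha01 / (alpha01 + alpha02), administrative
#' censoring at the group-specific time from
#' [censoring_time_for_fraction()] (events at the censoring time precede
#' the censoring).  All subjects start in state "0" at time 0; causes are
#' states "1" and "2".
#'
#' @param scenario a [competing_risks_scenario()].
#' @return a list with [event_records()] tables `group1` and `group2`.
#' @export
simulate_two_sample_competing_risks <- function(scenario) {
  stopifnot(inherits(scenario, "cr_scenario"))
  one_group <- function(hz, n, prefix) {
    lambda <- sum(hz)
    cens_at <- censoring_time_for_fraction(lambda,
                                           scenario$censoring_fraction)
    tt <- stats::rexp(n, lambda)
    cause <- ifelse(stats::runif(n) < hz[1] / lambda, "1", "2")
    exit <- pmin(tt, cens_at)
    to <- ifelse(tt <= cens_at, cause, CENSORED)
    event_records(paste0(prefix, seq_len(n)), 0, exit, "0", to)
  }
  with_seed(scenario$seed, {
    g1 <- one_group(scenario$hazards_group1, scenario$n_per_group, "g1_")
    g2 <- one_group(scenario$hazards_group2, scenario$n_per_group, "g2_")
    list(group1 = g1, group2 = g2)
  })
}

#' Synthetic multistate increment template
#'
#' A discrete-time template for the illness-death model with recovery
#' (states "0" healthy, "1" ill, "2" absorbing; transitions 0 -> 1,
#' 1 -> 0, 0 -> 2, 1 -> 2).  Per transition it stores *discrete hazard
#' increments* on a finite time grid -- the conditional probability of
#' making that transition at a grid time given occupancy of the source
#' state just before it -- so the true cumulative hazard of the generator
#' is simply the cumulative sum of the masses.  Initial-state and
#' censoring-time distributions are probability vectors (the censoring
#' distribution keeps its residual mass at `Inf`, i.e. "not censored
#' within the horizon").  The template is a synthetic stand-in generated
#' from smooth parametric hazard shapes with seeded multiplicative
#' jitter; it emulates the *structure* of templates built from real-data
#' increments, not any particular dataset.
#'
#' @param config optional list overriding `horizon` (default 30),
#'   `n_times` (default 40), `totals` (named cumulative-hazard totals per
#'   transition at the horizon), `initial` (initial distribution over
#'   states "0" and "1"), `censor_total` (probability of censoring within
#'   the horizon, default 0.3).
#' @param seed RNG seed for the jitter.
#' @return an object of class `"multistate_template"`.
#' @export
make_synthetic_template <- function(config = list(), seed = 1L) {
  horizon <- config$horizon %||% 30
  n_times <- config$n_times %||% 40L
  totals <- config$totals %||% c("0->1" = 0.35, "1->0" = 0.5,
                                 "0->2" = 1.3, "1->2" = 0.9)
  initial <- config$initial %||% c("0" = 0.75, "1" = 0.25)
  censor_total <- config$censor_total %||% 0.3
  times <- seq(horizon / n_times, horizon, length.out = n_times)
  shapes <- list(
    "0->1" = stats::dgamma(times, shape = 2, rate = 0.25),
    "1->0" = stats::dgamma(times, shape = 1.5, rate = 0.15),
    "0->2" = stats::dgamma(times, shape = 1.2, rate = 0.10),
    "1->2" = stats::dgamma(times, shape = 2.5, rate = 0.20)
  )
  hazards <- with_seed(seed, {
    lapply(names(shapes), function(tr) {
      s <- shapes[[tr]] * exp(stats::rnorm(n_times, sd = 0.15))
      s / sum(s) * totals[[tr]]
    })
  })
  names(hazards) <- names(shapes)
  # per-source-state total discrete hazard must stay below 1 at each time
  for (st in c("0", "1")) {
    out <- hazards[startsWith(names(hazards), paste0(st, "->"))]
    tot <- Reduce(`+`, out)
    if (max(tot) >= 0.9) {
      sc <- 0.9 / max(tot)
      hazards[names(out)] <- lapply(out, function(h) h * sc)
    }
  }
  cens_shape <- exp(-times / (horizon / 2))
  cens_mass <- cens_shape / sum(cens_shape) * censor_total
  structure(
    list(states = c("0", "1", "2"), absorbing = "2", times = times,
         initial = initial / sum(initial), hazards = hazards,
         censoring = list(times = c(times, Inf),
                          mass = c(cens_mass, 1 - censor_total)),
         horizon = horizon),
    class = "multistate_template"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True cumulative hazard of a template transition
#'
#' @param template a [make_synthetic_template()] template.
#' @param from,to transition state labels.
#' @return a [step_function()]: the cumulative sum of the increment masses.
#' @export
template_true_hazard <- function(template, from, to) {
  key <- paste0(from, "->", to)
  h <- template$hazards[[key]]
  if (is.null(h)) stop("template has no transition ", key)
  step_function(template$times, cumsum(h))
}

#' Simulate multistate event histories from an increment template
#'
#' Nested competing-risks sampling: each subject starts in a state drawn
#' from the initial distribution and carries a censoring time drawn from
#' the censoring distribution; given the current state and current time
#' only (Markov by construction), the next transition time is the first
#' grid time at which a uniform draw falls below the total discrete
#' out-hazard, and the destination is drawn proportionally to the
#' per-transition increments at that time.  Sojourns stop at absorption,
#' censoring, or the horizon.
#'
#' @param template a [make_synthetic_template()] template.
#' @param n number of subjects.
#' @param seed RNG seed.
#' @return an [event_records()] table (one row per sojourn).
#' @export
simulate_multistate_from_template <- function(template, n, seed = 1L) {
  stopifnot(inherits(template, "multistate_template"), n >= 1)
  tr_names <- names(template$hazards)
  tr_from <- sub("->.*$", "", tr_names)
  tr_to <- sub("^.*->", "", tr_names)
  times <- template$times
  with_seed(seed, {
    init <- sample(names(template$initial), n, replace = TRUE,
                   prob = template$initial)
    cidx <- sample.int(length(template$censoring$times), n, replace = TRUE,
                       prob = template$censoring$mass)
    cens_time <- template$censoring$times[cidx]
    rows <- vector("list", 4L * n)
    nr <- 0L
    for (i in seq_len(n)) {
      state <- init[i]
      tcur <- 0
      cap <- min(cens_time[i], template$horizon)
      repeat {
        if (state %in% template$absorbing) break
        out <- which(tr_from == state)
        cand <- which(times > tcur)
        ev_time <- NA_real_
        if (length(out) && length(cand)) {
          hmat <- vapply(out, function(j) template$hazards[[j]][cand],
                         numeric(length(cand)))
          hmat <- matrix(hmat, nrow = length(cand))
          htot <- rowSums(hmat)
          hit <- which(stats::runif(length(cand)) < htot)
          if (length(hit)) {
            k <- hit[1L]
            ev_time <- times[cand[k]]
            dest <- tr_to[out[sample.int(length(out), 1L,
                                         prob = hmat[k, ])]]
          }
        }
        if (is.na(ev_time) || ev_time > cap) {
          if (cap > tcur) {
            nr <- nr + 1L
            rows[[nr]] <- list(id = i, entry = tcur, exit = cap,
                               from = state, to = CENSORED)
          }
          break
        }
        nr <- nr + 1L
        rows[[nr]] <- list(id = i, entry = tcur, exit = ev_time,
                           from = state, to = dest)
        tcur <- ev_time
        state <- dest
        if (tcur >= cap) break
      }
    }
    rows <- rows[seq_len(nr)]
    event_records(
      vapply(rows, `[[`, numeric(1), "id"),
      vapply(rows, `[[`, numeric(1), "entry"),
      vapply(rows, `[[`, numeric(1), "exit"),
      vapply(rows, `[[`, character(1), "from"),
      vapply(rows, `[[`, character(1), "to")
    )
  })
}

#' Monte-Carlo size study for the proportionality test
#'
#' Repeatedly simulates the two-group competing-risks scenario, applies
#' [proportionality_test()] to the type-1 (0 -> 1) transition on
#' `[0, tau]`, and reports the rejection fraction.  Study index and
#' bootstrap stream both feed the seed derivation, so individual studies
#' are independent and reproducible.
#'
#' @param scenario a [competing_risks_scenario()].
#' @param n_studies number of simulated studies.
#' @param B bootstrap draws per study.
#' @param alpha nominal level.
#' @param rho `"KS"` or `"CvM"`.
#' @param spec a [multiplier_spec()] (its family is used; stream seeds are
#'   derived per study from `seed`).
#' @param seed root seed of the whole study.
#' @param transition `c(from, to)` transition under test.
#' @return a one-row `data.frame` with the configuration and the
#'   empirical rejection rate.
#' @export
run_size_study <- function(scenario, n_studies = 1000L, B = 1000L,
                           alpha = 0.05, rho = c("KS", "CvM"),
                           spec = multiplier_spec(), seed = 1L,
                           transition = c("0", "1")) {
  rho <- match.arg(rho)
  rejections <- 0L
  for (i in seq_len(n_studies)) {
    sc <- scenario
    sc$seed <- derive_seed(seed, "data", i)
    dat <- simulate_two_sample_competing_risks(sc)
    cd1 <- build_counting_data(dat$group1, transition[1], transition[2],
                               tau = scenario$tau, n = scenario$n_per_group)
    cd2 <- build_counting_data(dat$group2, transition[1], transition[2],
                               tau = scenario$tau, n = scenario$n_per_group)
    sp <- multiplier_spec(spec$family, derive_seed(seed, "boot", i))
    tst <- proportionality_test(cd1, cd2, rho, alpha, B,
                                tau = scenario$tau, spec = sp)
    rejections <- rejections + as.integer(tst$reject)
  }
  data.frame(scenario = scenario$scenario,
             n_per_group = scenario$n_per_group, tau = scenario$tau,
             rho = rho, multiplier = spec$family, B = as.integer(B),
             alpha = alpha, n_studies = as.integer(n_studies),
             n_rejections = rejections,
             rejection_rate = rejections / n_studies,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo coverage study for confidence bands
#'
#' Simulates a one-transition constant-hazard model (true cumulative
#' hazard `A(t) = hazard * t`) with optional administrative censoring and
#' reports, per band type, the fraction of studies in which the band
#' covers the truth over the *whole* interval.  The coverage check is
#' exact for the piecewise-constant band: on every segment the lower limit
#' is compared at the left end and the upper limit at the right end of
#' the segment, where the increasing truth is extremal.
#'
#' Besides the five band types of [band_spec()], the pseudo-type
#' `"pointwise"` constructs log-transformed pointwise `1 - alpha`
#' intervals (normal quantile, Aalen variance) and evaluates them
#' *simultaneously* -- the deliberately wrong reading whose coverage
#' collapses well below nominal, quantifying why genuine bands are needed.
#'
#' Band types whose mean observed event count falls below
#' `min_events` (default 20) are flagged as unreliable in the output.
#'
#' @param n subjects per study.
#' @param hazard constant transition hazard.
#' @param interval band interval `c(t1, t2)`.
#' @param band_types character vector of band types (see above).
#' @param n_studies number of simulated studies.
#' @param B bootstrap draws per study (wild-bootstrap types).
#' @param alpha band level.
#' @param multiplier a [multiplier_spec()].
#' @param censoring_fraction target censored fraction, or `NULL` for none.
#' @param seed root seed.
#' @param bb_paths,bb_grid Brownian-bridge Monte-Carlo settings for the
#'   `_a` types.
#' @param min_events flag threshold for the mean event count.
#' @return a `data.frame` with one row per band type: empirical coverage,
#'   mean event count and the reliability flag.
#' @export
run_coverage_study <- function(n = 200L, hazard = 1, interval = c(0.2, 1),
                               band_types = c("EP_w", "HW_w"),
                               n_studies = 1000L, B = 1000L, alpha = 0.05,
                               multiplier = multiplier_spec(),
                               censoring_fraction = 0.25, seed = 1L,
                               bb_paths = 1000L, bb_grid = 1000L,
                               min_events = 20) {
  tau <- interval[2]
  cens_at <- if (is.null(censoring_fraction)) Inf else
    censoring_time_for_fraction(hazard, censoring_fraction)
  covered <- stats::setNames(numeric(length(band_types)), band_types)
  attempted <- stats::setNames(numeric(length(band_types)), band_types)
  events_sum <- 0
  z <- stats::qnorm(1 - alpha / 2)
  for (i in seq_len(n_studies)) {
    rec <- with_seed(derive_seed(seed, "cov", i), {
      tt <- stats::rexp(n, hazard)
      exit <- pmin(tt, cens_at)
      to <- ifelse(tt <= cens_at, "1", CENSORED)
      event_records(seq_len(n), 0, exit, "0", to)
    })
    cd <- build_counting_data(rec, "0", "1", tau = tau, n = n)
    fit <- na_fit(cd)
    events_sum <- events_sum + fit$n_events
    needs_wb <- any(band_types %in% c("EP_w", "HW_w", "dir_w"))
    draws <- if (needs_wb) {
      sp <- multiplier_spec(multiplier$family, derive_seed(seed, "wb", i))
      wild_bootstrap_paths(cd, sp, B)
    }
    for (bt in band_types) {
      ok <- tryCatch({
        if (bt == "pointwise") {
          pts <- sup_grid(fit$estimate$times, interval)
          a <- eval_step(fit$estimate, pts)
          if (a[1] <= 0) stop("no event before t1")
          s2 <- eval_step(fit$var_aalen, pts)
          half <- z * sqrt(s2) / (sqrt(n) * a)
          band <- list(times = pts, lower = a * exp(-half),
                       upper = a * exp(half))
        } else {
          sp <- band_spec(bt, alpha, interval, multiplier = multiplier,
                          B = B, bb_paths = bb_paths, bb_grid = bb_grid)
          band <- na_confidence_band(fit, sp, draws = draws)
        }
        seg_end <- c(band$times[-1L], interval[2])
        all(band$lower <= hazard * band$times + 1e-12) &&
          all(band$upper >= hazard * seg_end - 1e-12)
      }, error = function(e) NA)
      if (!is.na(ok)) {
        attempted[bt] <- attempted[bt] + 1
        covered[bt] <- covered[bt] + as.numeric(ok)
      }
    }
  }
  mean_events <- events_sum / n_studies
  data.frame(band_type = band_types,
             coverage = as.numeric(covered / pmax(attempted, 1)),
             n_studies = as.integer(attempted),
             mean_events = mean_events,
             flagged = mean_events < min_events,
             row.names = NULL, stringsAsFactors = FALSE)
}
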