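---
title: "Wild-bootstrap inference for Nelson-Aalen estimators: methods and design"
author: "wildna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wild-bootstrap inference for Nelson-Aalen estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildna)
```

## The model

`wildna` performs nonparametric inference for cumulative transition
hazards $A_j(t) = \int_0^t \alpha_j(s)\,ds$ in event-history models whose
counting processes $N_j$ obey Aalen's multiplicative intensity model:
$\lambda_j(t) = \alpha_j(t) Y_j(t)$, with $Y_j$ the predictable at-risk
process. This covers Markovian multistate models with finite state space
(competing risks, illness-death with recovery, ...), relative and excess
mortality models, and certain semi-Markov situations, with independent
right-censoring and left-truncation.

The Nelson-Aalen estimator is the cumulative sum of $\Delta N_j / Y_j$
over observed jump times. Its normalized error process
$W_n = \sqrt{n}(\hat A - A)$ is asymptotically a Gaussian martingale with
variance function estimated either by the Aalen-type form
$n \sum \Delta N / Y^2$ or the Greenwood-type form
$n \sum (Y - \Delta N)\,\Delta N / Y^3$.

## The wild bootstrap

Inference is calibrated by resampling the *increments*: the bootstrap
process replaces the unobservable martingale increments with observed
increments multiplied by i.i.d. white-noise weights $G$ with mean 0 and
variance 1,
$$\hat W_n(t) = \sqrt{n} \int_0^t \frac{J(s)}{Y(s)}\,G(s)\,dN(s),$$
keeping the data fixed. Two weight families are provided: standard
normal, and centred Poisson(1), whose skewness of one can improve
small-sample behaviour.

Two design points deserve emphasis:

* **One multiplier per unit event.** A subject may experience many
  transitions, so weights are attached to event increments, not to
  subjects; a tied jump of size $\Delta N$ consumes $\Delta N$
  independent weights. A single time-constant weight per subject
  produces the wrong covariance structure in multistate models and is
  deliberately not offered.
* **Martingale structure.** Conditional on the data, $\hat W_n$ is a
  mean-zero square-integrable martingale whose predictable variation is
  exactly the Aalen-type variance estimator. The test suite verifies
  this variation matching, the conditional mean zero, and the increment
  orthogonality empirically at $B = 10{,}000$ draws.

Only weights at observed event times are ever materialized; the
white-noise process is never simulated on a continuum, because the
bootstrap integral only sees the jumps of $N$.

## Confidence bands

On an interval $[t_1, t_2]$ the package builds the five classical
time-simultaneous bands: log-transformed equal-precision (`EP`, weight
$g_1(s) = (s(1-s))^{-1/2}$) and Hall-Wellner (`HW`, $g_2 \equiv 1$)
bands with critical values from either the time-transformed Brownian
bridge (`_a`) or the wild bootstrap (`_w`), plus the untransformed
linear band `dir_w`. Supremum statistics are evaluated exactly on the
jump grid (plus $t_1$): the underlying processes are constant between
jumps, so no approximation grid is involved.

Defaults follow accuracy considerations observed in simulation: the
Brownian-bridge calibration uses the Greenwood-type variance estimate,
the wild-bootstrap calibration the empirical variance of the bootstrap
replicates (the uncentered second moment; the conditional mean is
exactly zero by construction, and a centered version is available by
argument). Brownian-bridge quantiles use 1000 simulated paths by
default, on a 1000-point uniform grid.

Within-sample difference bands, simultaneous confidence intervals over a
finite set of times, and Sidak-corrected joint regions across
transitions reuse the same machinery; two-sample equality and
proportional-hazards tests employ the rate factor $\sqrt{n_1 n_2 / n}$
and group-wise independent multiplier streams.

## Numerical choices

* **Brownian-bridge simulation.** Paths are generated by the Markov
  conditional recursion on the grid (exact Gaussian marginals at every
  grid point), in memory chunks. A plain grid maximum underestimates a
  continuum supremum, so by default the in-cell extremes are sampled
  from their closed-form conditional law, which removes the
  discretization bias: the simulated 95% point of $\sup |B^0|$ matches
  the Kolmogorov-distribution value 1.3581 to Monte-Carlo error already
  on moderate grids. For the weighted supremum the weight is frozen at
  the larger cell-endpoint value - exact for $g_2$, very slightly
  conservative for $g_1$ on a fine grid. Degenerate intervals use the
  exact normal marginal and no grid at all.
* **Equal-precision domain guard.** $g_1$ is unbounded at 0 and 1, and
  the transformed bands require $\hat A(t_1) > 0$. The package requires
  $\hat\phi \in [10^{-3}, 1 - 10^{-3}]$ over the interval for EP
  calibration and refuses intervals starting before the first event for
  the log-transformed bands, with guidance to move $t_1$ right. The
  $10^{-3}$ guard is an implementation choice; no published threshold
  exists.
* **Quantile and p-value rules.** Bootstrap critical values take the
  $\lceil (1-\alpha) B \rceil$-th order statistic (conservative,
  distribution-free); p-values use the add-one rule
  $(1 + \#\{\text{draws} \ge T\})/(B + 1)$, which never returns zero.
  The two rules can disagree on a knife edge one bootstrap order
  statistic wide (probability about $1/B$); the decision reported is
  the quantile comparison.
* **Tie conventions.** Events precede censorings at tied times by
  default (the censored subject counts as at risk); the opposite
  convention is available as `censoring_ties = "censor-first"`. Times
  are compared exactly; there is no binning.
* **Equivalence test.** Containment in the margin region is strict, the
  region being open; the two one-sided limits are taken at level
  $1-\alpha$ each, the standard intersection-union construction. The
  check augments all step-function knots with a 201-point grid to guard
  against strictly increasing continuous reference functions.
* **Seeding.** A single root seed derives independent streams per
  transition, bootstrap stream, and simulated study through a
  murmur-style avalanche hash, and all internal streams use the
  L'Ecuyer-CMRG generator, which is designed for creating many
  decorrelated streams. (Mersenne-Twister's single-integer seeding
  mixes too slowly for thousands of freshly seeded short streams and
  measurably distorted Monte-Carlo operating characteristics in
  development testing.) Runs are reproducible and order-independent,
  and study $i$ of a harness can be regenerated in isolation.

## The simulation harnesses

`simulate_two_sample_competing_risks()` realises the two-group
constant-hazard competing-risks designs: per subject an
Exponential($\alpha_{01} + \alpha_{02}$) event time, cause 1 with
probability $\alpha_{01}/(\alpha_{01}+\alpha_{02})$, and group-specific
administrative censoring at the closed-form time
$c = -\log(f)/\lambda$ that leaves a fraction $f$ (default 25%, applied
per group) censored. The four preset scenarios keep the competing
hazard at 2 in both groups and set the type-1 hazards to (2,2), (1,2),
(1,1) and (1,1.5). All four satisfy the proportional-hazards null
(constant hazards are trivially proportional), so
`run_size_study()` measures empirical size; defaults mirror the
benchmark design ($\tau = 0.3$, 1000 studies, 1000 bootstrap draws,
$\alpha = 0.05$).

`make_synthetic_template()` builds a discrete-time increment template
for the illness-death model with recovery. Per transition it stores
*discrete hazard increments* on a finite grid - the conditional
probability of that transition at a grid time given occupancy of the
source state - so the generator's true cumulative hazard is the
cumulative sum of the masses. Initial states and censoring times are
multinomial draws from probability vectors. Sampling is
sojourn-by-sojourn given the current state and time only, hence Markov
by construction. The template is generated from smooth gamma-shaped
hazards with seeded jitter: it emulates the *structure* of templates
derived from real cohort increments (finitely many support points,
unequal transition intensities, administrative-plus-random censoring),
not any particular dataset. Features of real registry data it does not
emulate include covariate heterogeneity, delayed study entry patterns
and recording artefacts - passing coverage tests on these synthetic
conditions demonstrates correct calibration of the machinery, not
robustness to those complications.

`run_coverage_study()` reports, per band type, the fraction of studies
in which the band covers the truth over the whole interval. The check
is exact for piecewise-constant bands against an increasing truth
(lower limits compared at segment starts, upper limits at segment
ends). A pseudo-type `"pointwise"` constructs log-transformed pointwise
intervals and evaluates them simultaneously - deliberately the wrong
reading, whose collapsing coverage (about 0.7 at $n = 200$) quantifies
why genuine bands are needed. Band types averaging fewer than 20
observed events are flagged as unreliable rather than suppressed.

## Problem sizes used by the shipped studies

The acceptance script and the heavy test cases run 1000 studies with
1000 bootstrap draws for the $n_i = 125$ size benchmarks, 400 studies
with 400 draws for the $n_i = 1000$ configuration, 1000 studies at
$B = 1000$ for band coverage at $n = 200$, 1000 studies at $B = 500$
for the equality-test sizes, and $10^5$ Brownian-bridge paths for the
Kolmogorov benchmark. These replication counts put the binomial
Monte-Carlo standard error of an empirical size near 0.05 at about
0.007.

## Known limitations

* No kernel-smoothed hazard estimation, Kaplan-Meier or Aalen-Johansen
  transition probabilities; the package stops at cumulative hazards.
* Only the log and identity band transformations are offered.
* The equivalence test's one-sided level choice ($1-\alpha$ per side)
  is the standard intersection-union reading; a Bonferroni-style
  $1-\alpha/2$ variant can be obtained by passing bands at that level.
* Multiplier families beyond standard normal and centred Poisson(1)
  are not built in; the theory requires mean 0, variance 1 and
  sufficient moments, and user-supplied families can be emulated by
  passing explicit multiplier matrices.
* The proportionality test conditions on $\hat A^{(1)} > 0$; with very
  few events in sample 1 the weighted statistic degenerates and the
  function errors rather than guessing.

## A worked example

```{r, eval = FALSE}
rec <- read_event_history("cohort.csv")
cd <- build_counting_data(rec, from = "1", to = "2", tau = 30)
fit <- na_fit(cd)
draws <- wild_bootstrap_paths(cd, multiplier_spec("normal", 2026), B = 1000)
spec <- band_spec("EP_w", alpha = 0.05, interval = c(5, 30))
band <- na_confidence_band(fit, spec, draws = draws)
write_band(band, "band_1_2_EP_w.csv")
```

The same analyses are scriptable from a shell through the thin wrapper
in `inst/cli/wildna` (`bands`, `test` and `simulate` subcommands).
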