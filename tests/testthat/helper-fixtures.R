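# Shared fixtures, built in code.

# Three-subject toy history: events of 0 -> 2 at times 1 and 2, one
# censoring at 2.5.  Jump grid (1, 2), dN = (1, 1), Y = (3, 2).
toy_records <- function() {
  event_records(c("id1", "id2", "id3"), 0, c(1, 2, 2.5), "0",
                c("2", "2", "cens"))
}

toy_cd <- function(tau = 3) {
  build_counting_data(toy_records(), "0", "2", tau = tau, n = 3)
}

toy_fit <- function(tau = 3) na_fit(toy_cd(tau))

# One-transition constant-hazard sample with administrative censoring.
simulate_survival <- function(n, hazard = 1, cens_at = Inf, seed = 1) {
  withr::local_seed(seed)
  tt <- rexp(n, hazard)
  exit <- pmin(tt, cens_at)
  to <- ifelse(tt <= cens_at, "1", "cens")
  event_records(seq_len(n), 0, exit, "0", to)
}

# Kolmogorov distribution function P(sup |B0| <= x), the analytic oracle
# for the unweighted Brownian-bridge supremum.
kolmogorov_cdf <- function(x, terms = 100) {
  k <- seq_len(terms)
  1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
}

kolmogorov_quantile <- function(p) {
  uniroot(function(x) kolmogorov_cdf(x) - p, c(0.3, 3), tol = 1e-10)$root
}
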