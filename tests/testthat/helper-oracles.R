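# Brute-force oracles for the JZS Bayes factors, independent of the
# package's quadrature path: dense-grid trapezoid integration of the
# defining marginal-likelihood integrals over the effect size delta.
# marginal likelihood of t under delta ~ (possibly truncated) Cauchy(0, r):
#   m = integral f_nu(t | delta * sqrt(n)) * prior(delta) d delta

trapz_oracle <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

nct_lik <- function(t, df, n_eff, delta)
  suppressWarnings(stats::dt(t, df = df, ncp = delta * sqrt(n_eff)))

# grid wide enough that the likelihood-weighted Cauchy tail is negligible
oracle_grid <- function(t, df, n_eff, r, n_pts = 100001L) {
  d_hat <- t / sqrt(n_eff)
  lik_w <- sqrt(1 / n_eff + d_hat^2 / (2 * df))
  half <- abs(d_hat) + 25 * lik_w + 5 * r
  seq(-half, half, length.out = n_pts)
}

oracle_bf_point <- function(t, df, n_eff, r) {
  d <- oracle_grid(t, df, n_eff, r)
  m1 <- trapz_oracle(d, nct_lik(t, df, n_eff, d) * stats::dcauchy(d, 0, r))
  m0 <- stats::dt(t, df = df)
  m1 / m0
}

oracle_bf_interval <- function(t, df, n_eff, r, c) {
  stopifnot(c > 0)
  p_in <- stats::pcauchy(c, 0, r) - stats::pcauchy(-c, 0, r)
  # inside: its own dense grid so small intervals stay resolved
  d_in <- seq(-c, c, length.out = 40001L)
  m0 <- trapz_oracle(d_in, nct_lik(t, df, n_eff, d_in) *
                       stats::dcauchy(d_in, 0, r) / p_in)
  # outside: two half-intervals out to the wide grid edge
  edge <- max(abs(oracle_grid(t, df, n_eff, r))) + c
  m1 <- 0
  for (side in list(c(-edge, -c), c(c, edge))) {
    d_out <- seq(side[1L], side[2L], length.out = 100001L)
    m1 <- m1 + trapz_oracle(d_out, nct_lik(t, df, n_eff, d_out) *
                              stats::dcauchy(d_out, 0, r) / (1 - p_in))
  }
  m1 / m0
}

# random test configurations under a fixed seed
random_bf_configs <- function(n, seed, interval = FALSE) {
  set.seed(seed)
  cfg <- data.frame(
    t = stats::runif(n, -6, 6),
    n1 = sample(5:40, n, replace = TRUE),
    r = stats::runif(n, 0.4, 1.5))
  cfg$df <- cfg$n1 - 1
  cfg$n_eff <- cfg$n1
  if (interval) cfg$c <- stats::runif(n, 0.05, 0.5)
  cfg
}
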