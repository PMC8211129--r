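test_that("posterior probabilities follow the posterior-odds rule", {
  pp <- bf_to_posterior(5, prior_odds = 1)
  expect_equal(pp$pp_h1, 5 / 6, tolerance = 1e-15)
  expect_equal(pp$pp_h0, 1 / 6, tolerance = 1e-15)

  pp <- bf_to_posterior(1)
  expect_equal(pp$pp_h1, 0.5)
  expect_equal(pp$pp_h0, 0.5)

  pp <- bf_to_posterior(2, prior_odds = 3) # posterior odds 6
  expect_equal(pp$pp_h1, 6 / 7)

  for (bf in c(0.01, 0.3, 1, 7, 1e4)) {
    pp <- bf_to_posterior(bf, prior_odds = 0.7)
    expect_equal(pp$pp_h0 + pp$pp_h1, 1, tolerance = 1e-12)
  }
  expect_error(bf_to_posterior(-1), "positive")
  expect_error(bf_to_posterior(2, prior_odds = 0), "positive")
})

test_that("Cauchy prior mass: half the mass lies within one scale unit", {
  for (r in c(sqrt(2) / 2, 1, sqrt(2)))
    expect_equal(cauchy_prior_mass(r, -r, r), 0.5, tolerance = 1e-15)
  expect_equal(cauchy_prior_mass(1, -Inf, Inf), 1)
  expect_equal(cauchy_prior_mass(1, 0, 1), 0.25, tolerance = 1e-15)
  expect_error(cauchy_prior_mass(-1, 0, 1), "positive")
  expect_error(cauchy_prior_mass(1, 2, 1), "a <= b")
})

test_that("named prior scales resolve to the standard values", {
  expect_equal(prior_scale("medium"), sqrt(2) / 2)
  expect_equal(prior_scale("wide"), 1)
  expect_equal(prior_scale("ultrawide"), sqrt(2))
  expect_error(prior_scale("enormous"))
  expect_error(prior_spec(r = 0), "positive")
})

test_that("point-null quadrature matches the dense-grid oracle", {
  cfg <- random_bf_configs(20, seed = 2024)
  for (i in seq_len(nrow(cfg))) {
    bf <- jzs_bf_point(t_statistic(cfg$t[i], cfg$df[i], cfg$n_eff[i]),
                       prior_spec(cfg$r[i]))
    oracle <- oracle_bf_point(cfg$t[i], cfg$df[i], cfg$n_eff[i], cfg$r[i])
    expect_equal(bf$bf10, oracle, tolerance = 1e-6,
                 label = sprintf("config %d (t=%.2f)", i, cfg$t[i]))
    expect_equal(bf$bf01 * bf$bf10, 1, tolerance = 1e-12)
  }
})

test_that("interval-null quadrature matches the truncated-prior oracle", {
  cfg <- random_bf_configs(20, seed = 2025, interval = TRUE)
  for (i in seq_len(nrow(cfg))) {
    bf <- jzs_bf_interval(t_statistic(cfg$t[i], cfg$df[i], cfg$n_eff[i]),
                          prior_spec(cfg$r[i], c = cfg$c[i]))
    oracle <- oracle_bf_interval(cfg$t[i], cfg$df[i], cfg$n_eff[i],
                                 cfg$r[i], cfg$c[i])
    expect_equal(bf$bf10, oracle, tolerance = 1e-5,
                 label = sprintf("config %d (t=%.2f, c=%.2f)",
                                 i, cfg$t[i], cfg$c[i]))
  }
  # the spec's pinned example config against the oracle
  bf <- jzs_bf_interval(t_statistic(2.5, 9, 10), prior_spec(sqrt(2) / 2,
                                                            c = 0.2))
  expect_equal(bf$bf10, oracle_bf_interval(2.5, 9, 10, sqrt(2) / 2, 0.2),
               tolerance = 1e-5)
})

test_that("degenerate-prior and nested-model limits hold", {
  t <- t_statistic(3.3, 17, 18)
  # r -> 0: the alternative collapses onto the null, BF -> 1
  expect_equal(jzs_bf_point(t, prior_spec(1e-7))$bf10, 1, tolerance = 1e-4)
  # c -> 0: interval BF converges to the point BF
  pt <- jzs_bf_point(t, prior_spec("medium"))$bf10
  expect_equal(jzs_bf_interval(t, prior_spec("medium", c = 1e-5))$bf10,
               pt, tolerance = 1e-4)
  # c = 0 is rejected
  expect_error(jzs_bf_interval(t, prior_spec("medium", c = 0)), "c > 0")
})

test_that("point-null BF is even in t, increasing in |t|, scale-free", {
  prior <- prior_spec("medium")
  bfs <- vapply(seq(0, 8, by = 0.5), function(tv)
    jzs_bf_point(t_statistic(tv, 14, 15), prior)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0)) # strictly increasing in |t|
  for (tv in c(0.7, 2.1, 4.4))
    expect_equal(jzs_bf_point(t_statistic(-tv, 14, 15), prior)$bf10,
                 jzs_bf_point(t_statistic(tv, 14, 15), prior)$bf10,
                 tolerance = 1e-10)
  # scale invariance: t computed from x and from 10 * x is identical,
  # hence so is the BF
  set.seed(7)
  x <- rnorm(12, mean = 0.5)
  t1 <- mean(x) / (sd(x) / sqrt(12))
  t2 <- mean(10 * x) / (sd(10 * x) / sqrt(12))
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("BF is consistent: accumulating data drives it to its limit", {
  # median BF over replicates shrinks under the null and grows under
  # delta = 0.8 as n grows
  set.seed(11)
  med_bf <- function(delta, n, reps = 200) {
    bfs <- replicate(reps, {
      x <- rnorm(n, mean = delta)
      tv <- mean(x) / (sd(x) / sqrt(n))
      jzs_bf_point(t_statistic(tv, n - 1, n), prior_spec("medium"))$bf10
    })
    median(bfs)
  }
  null_trend <- vapply(c(10, 50, 200), med_bf, numeric(1), delta = 0)
  alt_trend <- vapply(c(10, 50, 200), med_bf, numeric(1), delta = 0.8)
  expect_true(all(diff(null_trend) < 0))
  expect_true(all(diff(alt_trend) > 0))
  expect_lt(null_trend[3], 0.2)
  expect_gt(alt_trend[3], 100)
})

test_that("delta posterior is a proper density with the right shape", {
  prior <- prior_spec(1)
  # t = 0, symmetric design: symmetric about 0
  p0 <- delta_posterior(t_statistic(0, 9, 10), prior)
  expect_equal(sum(p0$delta * p0$density) * mean(diff(p0$delta)), 0,
               tolerance = 1e-8)
  # normalization and nonnegativity for assorted inputs
  for (tv in c(-4, 0.5, 3)) {
    p <- delta_posterior(t_statistic(tv, 14, 15), prior)
    expect_true(all(p$density >= 0))
    grid_int <- sum((p$density[-1] + p$density[-length(p$density)]) / 2 *
                      diff(p$delta))
    expect_equal(grid_int, 1, tolerance = 1e-6)
  }
  # t = 3: posterior mass favours delta > 0
  p3 <- delta_posterior(t_statistic(3, 14, 15), prior)
  h <- mean(diff(p3$delta))
  expect_gt(sum(p3$density[p3$delta > 0]) * h,
            sum(p3$density[p3$delta < 0]) * h)
})

test_that("one-sided priors reweight the evidence by posterior sign mass", {
  t <- t_statistic(2.5, 9, 10)
  b2 <- jzs_bf_point(t, prior_spec("medium"))$bf10
  bp <- jzs_bf_point(t, prior_spec("medium", sided = "positive"))$bf10
  bn <- jzs_bf_point(t, prior_spec("medium", sided = "negative"))$bf10
  expect_gt(bp, b2)  # data agree with the directed alternative
  expect_lt(bn, b2)
  expect_equal((bp + bn) / 2, b2, tolerance = 1e-6) # mixture identity
})

test_that("invalid Bayes-factor inputs are rejected", {
  expect_error(t_statistic(Inf, 9, 10), "finite")
  expect_error(t_statistic(1, 0.5, 10), ">= 1")
  expect_error(t_statistic(1, 9, 0), "positive")
  expect_error(jzs_bf_point(1, prior_spec()), "t_statistic")
})
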