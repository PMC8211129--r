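make_ts <- function(m) trajectory_set(m)

test_that("nodewise t field matches hand-computed statistics", {
  # paired differences {1, 2, 3} at every node: t = 2 / (1 / sqrt(3))
  a <- make_ts(matrix(c(1, 2, 3), 3, 5) + 1)
  b <- make_ts(matrix(1, 3, 5))
  tf <- t_statistic_field(a, b, "paired")
  expect_equal(tf$t, rep(2 * sqrt(3), 5), tolerance = 1e-12)
  expect_equal(tf$dof, 2)
  expect_equal(tf$effective_n, 3)

  # two-sample: swapping groups negates the field; effective n pooled
  x <- smooth_gaussian_fields(5, 31, 8, seed = 3)
  y <- smooth_gaussian_fields(7, 31, 8, seed = 4)
  t_xy <- t_statistic_field(x, y, "two_sample")
  t_yx <- t_statistic_field(y, x, "two_sample")
  expect_equal(t_xy$t, -t_yx$t, tolerance = 1e-12)
  expect_equal(t_xy$dof, 10)
  expect_equal(t_xy$effective_n, 35 / 12)

  # identical paired data: zero variance is a degenerate-node error
  z <- make_ts(matrix(rnorm(12), 4, 3))
  expect_error(t_statistic_field(z, z, "paired"), "node 1")
})

test_that("q-values are cumulative means of sorted PEPs", {
  expect_equal(q_values(c(0.01, 0.02, 0.06)), c(0.01, 0.015, 0.03))
  # constant PEP: q equals that constant everywhere
  expect_equal(q_values(rep(0.3, 7)), rep(0.3, 7))
  # unsorted input: q follows the PEP order, not the node order
  pep <- c(0.06, 0.01, 0.02)
  expect_equal(q_values(pep), c(0.03, 0.01, 0.015))
})

test_that("q-values are monotone, bounded and permutation-equivariant", {
  set.seed(21)
  for (rep in 1:20) {
    pep <- runif(50)
    q <- q_values(pep)
    o <- order(pep)
    expect_true(all(diff(q[o]) >= -1e-15))
    expect_true(all(q <= max(pep) + 1e-15))
    expect_true(all(q <= pep + 1e-15)) # running mean of smaller values
    perm <- sample(50)
    expect_equal(q_values(pep[perm]), q[perm])
  }
  # ties share the q of their last tied rank (order-independent)
  pep <- c(0.2, 0.1, 0.1, 0.3)
  q <- q_values(pep)
  expect_equal(q[2], q[3])
  expect_equal(q[2], mean(c(0.1, 0.1)))
  expect_equal(q[1], mean(c(0.1, 0.1, 0.2)))
})

test_that("bayesian_spm builds a coherent posterior probability map", {
  g <- make_two_local_max(burst_amplitude = 5, burst_pct = c(24),
                          seed = 8)
  map <- bayesian_spm(g$group1, g$group2, "two_sample",
                      prior_spec("medium", c = 0.2), "interval")
  expect_s3_class(map, "ppm")
  expect_length(map$pp_h1, 101)
  expect_equal(map$pp_h0 + map$pp_h1, rep(1, 101), tolerance = 1e-12)
  expect_equal(map$pep_h1, map$pp_h0)
  expect_equal(map$q_h1, q_values(map$pep_h1))
  # the strong burst at 24% dominates the map near node 25
  peak <- which.max(map$pp_h1)
  expect_true(abs(peak - 25.24) < 6)
  expect_gt(map$pp_h1[peak], 0.95)

  # equal condition means (differences centred to zero): t = 0 at every
  # node, which favours the interval null everywhere
  x <- smooth_gaussian_fields(6, 41, 10, seed = 5)
  d <- smooth_gaussian_fields(6, 41, 10, seed = 6)$values
  d <- sweep(d, 2L, colMeans(d))
  map0 <- bayesian_spm(x, trajectory_set(x$values - d), "paired",
                       prior_spec("medium", c = 0.2), "interval")
  expect_equal(max(abs(map0$t)), 0, tolerance = 1e-10)
  expect_true(all(map0$pp_h0 > 0.5))
})

test_that("point and interval nulls agree when the evidence is decisive", {
  g <- make_two_local_max(burst_amplitude = 6, n_per_group = 10, seed = 12)
  pr <- prior_spec("medium", c = 0.2)
  m_pt <- bayesian_spm(g$group1, g$group2, "two_sample", pr, "point")
  m_iv <- bayesian_spm(g$group1, g$group2, "two_sample", pr, "interval")
  at_burst <- which.max(abs(m_pt$t))
  expect_gt(m_pt$pp_h1[at_burst], 0.99)
  expect_gt(m_iv$pp_h1[at_burst], 0.99)
})

test_that("cluster extraction reports 1-based inclusive node and percent runs", {
  fake_map <- function(pp_h1) {
    Q <- length(pp_h1)
    pep_h1 <- 1 - pp_h1
    structure(list(pp_h1 = pp_h1, pp_h0 = 1 - pp_h1,
                   pep_h1 = pep_h1, pep_h0 = pp_h1,
                   q_h1 = q_values(pep_h1), q_h0 = q_values(pp_h1),
                   Q = Q),
              class = "ppm")
  }
  m <- fake_map(c(0.99, 0.99, rep(0.2, 9)))
  cl <- extract_clusters(m, "H1", "pp_095")
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_node, 1L)
  expect_equal(cl$end_node, 2L)
  expect_equal(cl$start_pct, 0)
  expect_equal(cl$end_pct, 10)
  expect_equal(cl$extremum, 0.99)

  # nothing passes -> empty table
  expect_equal(nrow(extract_clusters(fake_map(rep(0.5, 11)), "H1",
                                     "pp_095")), 0L)

  # q rule records the largest admitted PEP
  clq <- extract_clusters(m, "H1", "q_005")
  expect_true(!is.null(attr(clq, "max_pep_admitted")))
  expect_lte(attr(clq, "max_pep_admitted"), max(m$pep_h1))
})

test_that("every PP>=0.95 cluster is nested inside a q<=0.05 cluster", {
  set.seed(33)
  fake_map <- function(pp_h1) {
    pep_h1 <- 1 - pp_h1
    structure(list(pp_h1 = pp_h1, pp_h0 = 1 - pp_h1,
                   pep_h1 = pep_h1, pep_h0 = pp_h1,
                   q_h1 = q_values(pep_h1), q_h0 = q_values(pp_h1),
                   Q = length(pp_h1)),
              class = "ppm")
  }
  for (rep in 1:100) {
    # random smooth-ish probability fields with occasional extremes
    Q <- sample(20:120, 1)
    pp <- stats::plogis(cumsum(rnorm(Q, sd = 1.2)))
    m <- fake_map(pp)
    for (h in c("H1", "H0")) {
      cl_pp <- extract_clusters(m, h, "pp_095")
      cl_q <- extract_clusters(m, h, "q_005")
      if (nrow(cl_pp) == 0) next
      nodes_pp <- unlist(mapply(seq, cl_pp$start_node, cl_pp$end_node,
                                SIMPLIFY = FALSE))
      nodes_q <- unlist(mapply(seq, cl_q$start_node, cl_q$end_node,
                               SIMPLIFY = FALSE))
      expect_true(all(nodes_pp %in% nodes_q))
    }
  }
})

test_that("hypothesis labels mirror cleanly", {
  set.seed(5)
  pp <- stats::plogis(cumsum(rnorm(60, sd = 1.5)))
  m1 <- structure(list(pp_h1 = pp, pp_h0 = 1 - pp, pep_h1 = 1 - pp,
                       pep_h0 = pp, q_h1 = q_values(1 - pp),
                       q_h0 = q_values(pp), Q = 60), class = "ppm")
  m2 <- structure(list(pp_h1 = 1 - pp, pp_h0 = pp, pep_h1 = pp,
                       pep_h0 = 1 - pp, q_h1 = q_values(pp),
                       q_h0 = q_values(1 - pp), Q = 60), class = "ppm")
  for (rule in c("pp_095", "q_005")) {
    a <- extract_clusters(m1, "H1", rule)
    b <- extract_clusters(m2, "H0", rule)
    expect_equal(a$start_node, b$start_node)
    expect_equal(a$end_node, b$end_node)
  }
})

test_that("wider priors never favour H1 more where |t| is small", {
  x <- smooth_gaussian_fields(8, 31, 10, seed = 9)
  y <- smooth_gaussian_fields(8, 31, 10, seed = 10)
  maps <- lapply(c("medium", "wide", "ultrawide"), function(r)
    bayesian_spm(x, y, "two_sample", prior_spec(r, c = 0.2), "interval"))
  small_t <- abs(maps[[1]]$t) < 1
  expect_true(any(small_t))
  expect_true(all(maps[[2]]$pp_h0[small_t] >=
                    maps[[1]]$pp_h0[small_t] - 1e-10))
  expect_true(all(maps[[3]]$pp_h0[small_t] >=
                    maps[[2]]$pp_h0[small_t] - 1e-10))
})

test_that("cluster tables use the fixed CSV schema", {
  g <- make_two_local_max(burst_amplitude = 5, seed = 2)
  map <- bayesian_spm(g$group1, g$group2, "two_sample",
                      prior_spec("medium", c = 0.2), "interval")
  tab <- ppm_cluster_table(map, dataset = "demo", r_label = "medium")
  expect_named(tab, c("dataset", "design", "null_type", "r_label",
                      "hypothesis", "rule", "start_node", "end_node",
                      "start_pct", "end_pct", "extremum"))
})
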