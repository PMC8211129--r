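#' Residual smoothness (FWHM) of a 1D field
#'
#' Estimates the full width at half maximum of the field's effective
#' Gaussian autocorrelation kernel from residual gradients, the standard
#' SPM estimator: residuals are scaled to unit norm at each node, gradients
#' are taken along the node axis (central differences in the interior,
#' one-sided at the ends), and
#' \deqn{\widehat{FWHM} = \sqrt{4 \ln 2 / \overline{g^2}}}
#' where \eqn{\overline{g^2}} is the mean over nodes of the per-node sum of
#' squared normalized gradients.
#'
#' @param residuals J x Q numeric matrix of residuals (paired design:
#'   nodewise-centred differences; two-sample: each group centred, stacked).
#' @param max_fwhm Cap returned when gradients vanish (default `10 * Q`).
#' @return Estimated FWHM in nodes.
#' @export
estimate_fwhm <- function(residuals, max_fwhm = 10 * ncol(residuals)) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 2L)
    stop("smoothness estimation needs J >= 2 residual rows", call. = FALSE)
  ss <- sqrt(colSums(residuals^2))
  if (all(ss == 0))
    stop("all-zero residuals: smoothness undefined", call. = FALSE)
  ss[ss == 0] <- .Machine$double.eps
  rn <- sweep(residuals, 2L, ss, "/")
  g <- field_gradient(rn)
  msg <- mean(colSums(g^2))
  if (msg <= 0) return(max_fwhm)
  min(sqrt(4 * log(2) / msg), max_fwhm)
}

# gradient along the node axis: central differences in the interior,
# one-sided at the field ends (unit node spacing)
field_gradient <- function(m) {
  Q <- ncol(m)
  g <- matrix(0, nrow(m), Q)
  g[, 1L] <- m[, 2L] - m[, 1L]
  g[, Q] <- m[, Q] - m[, Q - 1L]
  if (Q > 2L)
    g[, 2:(Q - 1L)] <- (m[, 3:Q] - m[, 1:(Q - 2L)]) / 2
  g
}

# Euler characteristic densities for a 1D t field at height u:
# ec0 = tail probability of t_nu, ec1 per resel
rft_ec <- function(u, nu, resel_count) {
  ec0 <- stats::pt(u, df = nu, lower.tail = FALSE)
  ec1 <- resel_count * sqrt(4 * log(2)) / (2 * pi) *
    (1 + u^2 / nu)^(-(nu - 1) / 2)
  list(ec0 = ec0, ec1 = ec1, total = ec0 + ec1)
}

#' RFT critical threshold for a smooth 1D t field
#'
#' The smallest height u at which the expected-Euler-characteristic
#' approximation to the field-maximum tail probability,
#' \deqn{P(\max_q T(q) \ge u) \approx P(T_\nu \ge u) +
#'   R\,\frac{\sqrt{4\ln 2}}{2\pi}\,(1 + u^2/\nu)^{-(\nu-1)/2},}
#' with resel count \eqn{R = (Q-1)/\mathrm{FWHM}}, equals `alpha`; solved by
#' monotone root finding.
#'
#' @param nu Degrees of freedom.
#' @param Q Number of field nodes.
#' @param fwhm Field smoothness in nodes.
#' @param alpha Tail probability, in (0, 0.5].
#' @return The critical threshold u.
#' @export
rft_critical_threshold <- function(nu, Q, fwhm, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5)
    stop("'alpha' must lie in (0, 0.5]", call. = FALSE)
  if (fwhm <= 0) stop("'fwhm' must be positive", call. = FALSE)
  resel_count <- (Q - 1) / fwhm
  f <- function(u) rft_ec(u, nu, resel_count)$total - alpha
  lo <- stats::qt(alpha, df = nu, lower.tail = FALSE) # EC >= alpha here
  if (f(100) > 0)
    stop("no RFT threshold found in (", round(lo, 2), ", 100]",
         call. = FALSE)
  stats::uniroot(f, lower = lo, upper = 100, tol = 1e-10)$root
}

#' RFT cluster-extent p-value for a 1D t field
#'
#' Probability that a smooth random t field of the given smoothness produces
#' a supra-threshold cluster at least as broad as observed. Uses the
#' standard Poisson-clumping approximation
#' \deqn{p = 1 - \exp\{-E[m]\, P(\mathrm{extent} \ge k)\},}
#' where E\[m\] is the expected number of supra-threshold clusters (the
#' expected Euler characteristic at u) and the extent distribution is
#' modeled exponentially, \eqn{P(\mathrm{extent} \ge k) = e^{-\lambda k}}
#' with rate \eqn{\lambda} equal to the expected number of upcrossings per
#' expected supra-threshold measure (both in resel units).
#'
#' @param extent_resels Observed cluster extent in resels (> 0).
#' @param u Threshold height at which clusters were defined.
#' @param nu Degrees of freedom.
#' @param resel_count Total field size in resels, `(Q - 1) / fwhm`.
#' @return The cluster p-value (one-tailed; [spm_t_test()] doubles it for
#'   two-tailed inference).
#' @export
cluster_p_value <- function(extent_resels, u, nu, resel_count) {
  if (extent_resels < 0) stop("'extent_resels' must be >= 0", call. = FALSE)
  ec <- rft_ec(u, nu, resel_count)
  e_clusters <- ec$total
  e_measure <- resel_count * stats::pt(u, df = nu, lower.tail = FALSE)
  lambda <- ec$ec1 / max(e_measure, .Machine$double.xmin)
  1 - exp(-e_clusters * exp(-lambda * extent_resels))
}

#' Classical SPM{t}: field-wide t test with RFT inference
#'
#' Computes the nodewise t field, estimates residual smoothness, derives the
#' two-tailed RFT critical threshold (alpha split equally across tails,
#' applied to |t|), extracts supra-threshold clusters (strict crossing,
#' extent counted in whole nodes converted to resels, no interpolation) and
#' attaches a cluster-extent p-value to each (doubled for two-tailedness,
#' capped at 1).
#'
#' @inheritParams t_statistic_field
#' @param alpha Field-wide Type I error rate (default 0.05).
#' @return An object of class `spm_t` with `t_field`, `dof`, `fwhm`,
#'   `resel_count`, `t_star`, `alpha` and a `clusters` data frame (columns
#'   `start_node`, `end_node`, `start_pct`, `end_pct`, `extent_nodes`,
#'   `extent_resels`, `sign`, `extremum`, `p_value`).
#' @examples
#' g <- make_two_local_max(burst_amplitude = 5, seed = 1)
#' spm_t_test(g$group1, g$group2, "two_sample")
#' @export
spm_t_test <- function(a, b, design = c("paired", "two_sample"),
                       alpha = 0.05) {
  design <- match.arg(design)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  tf <- t_statistic_field(a, b, design)
  res <- if (design == "paired") {
    d <- a$values - b$values
    sweep(d, 2L, colMeans(d))
  } else {
    rbind(sweep(a$values, 2L, colMeans(a$values)),
          sweep(b$values, 2L, colMeans(b$values)))
  }
  fwhm <- estimate_fwhm(res)
  resel_count <- (tf$Q - 1) / fwhm
  t_star <- rft_critical_threshold(tf$dof, tf$Q, fwhm, alpha / 2)

  clusters <- lapply(c(1, -1), function(sgn) {
    runs <- passing_runs(sgn * tf$t > t_star)
    if (nrow(runs) == 0L) return(NULL)
    ext_nodes <- runs$end - runs$start + 1L
    ext_resels <- ext_nodes / fwhm
    data.frame(
      start_node = runs$start, end_node = runs$end,
      start_pct = node_to_pct(runs$start, tf$Q),
      end_pct = node_to_pct(runs$end, tf$Q),
      extent_nodes = ext_nodes, extent_resels = ext_resels,
      sign = rep(sgn, nrow(runs)),
      extremum = vapply(seq_len(nrow(runs)), function(i)
        tf$t[runs$start[i]:runs$end[i]][
          which.max(sgn * tf$t[runs$start[i]:runs$end[i]])],
        numeric(1L)),
      p_value = pmin(1, 2 * vapply(ext_resels, cluster_p_value,
                                   numeric(1L), u = t_star, nu = tf$dof,
                                   resel_count = resel_count)))
  })
  clusters <- do.call(rbind, clusters)
  if (is.null(clusters))
    clusters <- data.frame(start_node = integer(), end_node = integer(),
                           start_pct = numeric(), end_pct = numeric(),
                           extent_nodes = integer(),
                           extent_resels = numeric(), sign = numeric(),
                           extremum = numeric(), p_value = numeric())
  clusters <- clusters[order(clusters$start_node), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(
    list(t_field = tf$t, dof = tf$dof, effective_n = tf$effective_n,
         Q = tf$Q, fwhm = fwhm, resel_count = resel_count, t_star = t_star,
         alpha = alpha, design = design, clusters = clusters),
    class = "spm_t")
}

#' @export
print.spm_t <- function(x, ...) {
  cat(sprintf(
    "SPM{t} (%s design): Q = %d, nu = %g, FWHM = %.2f nodes, t* = %.3f (alpha = %g, two-tailed)\n",
    x$design, x$Q, x$dof, x$fwhm, x$t_star, x$alpha))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster nodes %d-%d (%.0f-%.0f%%): extremum t = %.3f, p = %.3f\n",
                  x$clusters$start_node[i], x$clusters$end_node[i],
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$extremum[i], x$clusters$p_value[i]))
  }
  invisible(x)
}

#' Cluster table for a classical SPM{t} result
#'
#' Same CSV schema as [ppm_cluster_table()] plus a `p_value` column;
#' `hypothesis` is `"H1"` (evidence against the null) and `rule` is
#' `"rft_alpha"`.
#'
#' @param spm An [spm_t_test()] result.
#' @param dataset Text label for the `dataset` column.
#' @return Data frame.
#' @export
spm_cluster_table <- function(spm, dataset = "") {
  cl <- spm$clusters
  data.frame(dataset = rep(dataset, nrow(cl)),
             design = rep(spm$design, nrow(cl)),
             null_type = rep("point", nrow(cl)),
             r_label = rep("", nrow(cl)),
             hypothesis = rep("H1", nrow(cl)),
             rule = rep("rft_alpha", nrow(cl)),
             start_node = cl$start_node, end_node = cl$end_node,
             start_pct = cl$start_pct, end_pct = cl$end_pct,
             extremum = cl$extremum, p_value = cl$p_value,
             stringsAsFactors = FALSE)
}
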