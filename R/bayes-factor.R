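#' Summarize a t statistic for Bayes-factor computation
#'
#' The JZS Bayes factor depends on the data only through the t statistic,
#' its degrees of freedom and the effective sample size: `n` for a paired /
#' one-sample design, `n1 * n2 / (n1 + n2)` for a two-sample design (with
#' `dof = n1 + n2 - 2`).
#'
#' @param value The t statistic.
#' @param dof Degrees of freedom (>= 1).
#' @param effective_n Effective sample size (> 0).
#' @return An object of class `t_statistic`.
#' @examples
#' t_statistic(2.5, dof = 9, effective_n = 10)
#' @export
t_statistic <- function(value, dof, effective_n) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("t 'value' must be a single finite number", call. = FALSE)
  if (!is.numeric(dof) || length(dof) != 1L || !is.finite(dof) || dof < 1)
    stop("'dof' must be a single number >= 1", call. = FALSE)
  if (!is.numeric(effective_n) || length(effective_n) != 1L ||
      !is.finite(effective_n) || effective_n <= 0)
    stop("'effective_n' must be a single positive number", call. = FALSE)
  structure(list(value = as.numeric(value), dof = as.numeric(dof),
                 effective_n = as.numeric(effective_n)),
            class = "t_statistic")
}

LOG_BF_CAP <- 700

bf_result <- function(log_bf10, err = 0, capped = FALSE) {
  if (log_bf10 > LOG_BF_CAP) { log_bf10 <- LOG_BF_CAP; capped <- TRUE }
  if (log_bf10 < -LOG_BF_CAP) { log_bf10 <- -LOG_BF_CAP; capped <- TRUE }
  structure(list(bf10 = exp(log_bf10), bf01 = exp(-log_bf10),
                 log_bf10 = log_bf10,
                 numerical_error_estimate = as.numeric(err),
                 capped = capped),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("BF10 = %.6g (log BF10 = %.4f)%s\n", x$bf10, x$log_bf10,
              if (isTRUE(x$capped)) " [capped]" else ""))
  invisible(x)
}

# log noncentral-t density, vectorized over ncp. stats::dt loses (and
# warns about) precision beyond |ncp| = 37.62, and the warning signalling
# dominates runtime when hit inside quadrature loops; past that point the
# density is dozens of log units below the peak, so a Laplace
# approximation of the defining scale-mixture integral
#   f(x; nu, mu) = int_0^inf s phi(s x - mu) h_nu(s) ds,
# with h_nu the density of sqrt(chisq_nu / nu), is used instead (relative
# log error ~ 1/nu, irrelevant at those depths).
ldt_nc <- function(x, df, ncp) {
  # a statistic deep in the central-t tail (log density < -18) puts every
  # pnt evaluation in the regime where R's algorithm grinds through (and
  # warns about) a non-converging series; there the Bayes factor is
  # decisively large anyway, so the whole call uses the smooth Laplace
  # form, keeping ratios within the call consistent
  if (stats::dt(x, df = df, log = TRUE) < -18)
    return(ldt_nc_laplace(x, df, ncp))
  out <- ldt_nc_laplace(x, df, ncp)
  near <- abs(ncp) < 37
  # f(x; nu, ncp) = f(-x; nu, -ncp): R's pnt warns (slowly) for negative
  # noncentrality, so always evaluate on the non-negative side
  pos <- near & ncp >= 0
  neg <- near & ncp < 0
  if (any(pos))
    out[pos] <- stats::dt(x, df = df, ncp = ncp[pos], log = TRUE)
  if (any(neg))
    out[neg] <- stats::dt(-x, df = df, ncp = -ncp[neg], log = TRUE)
  out
}

ldt_nc_laplace <- function(x, nu, mu) {
  tx <- x * mu
  disc <- sqrt(tx^2 + 4 * nu * (x^2 + nu))
  s <- ifelse(tx > 0, (tx + disc) / (2 * (x^2 + nu)), 2 * nu / (disc - tx))
  L <- -(s * x - mu)^2 / 2 + nu * log(s) - nu * s^2 / 2
  d2 <- (x^2 + nu) + nu / s^2
  log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) + L - 0.5 * log(d2)
}

check_t_prior <- function(t, prior) {
  if (!inherits(t, "t_statistic"))
    stop("'t' must be a t_statistic object", call. = FALSE)
  if (!inherits(prior, "prior_spec"))
    stop("'prior' must be a prior_spec object", call. = FALSE)
}

# log integrand of the JZS marginal likelihood ratio over the mixing
# variance g, after substituting g = r^2 * s with s ~ InvGamma(1/2, 1/2)
# (the substitution makes the integrand well conditioned for any r,
# including the r -> 0 degenerate-prior limit).
jzs_log_integrand_s <- function(s, t, nu, n_eff, r2) {
  a <- 1 + n_eff * r2 * s
  -0.5 * log(a) - (nu + 1) / 2 * log1p(t^2 / (nu * a)) -
    0.5 * log(2 * pi) - 1.5 * log(s) - 1 / (2 * s)
}

#' JZS Bayes factor for a point null
#'
#' Default-prior Bayes factor BF10 comparing \eqn{H_1: \delta \sim
#' \mathrm{Cauchy}(0, r)} against the point null \eqn{H_0: \delta = 0} for a
#' t-design, computed by adaptive quadrature of the JZS mixing-variance
#' integral (the Cauchy prior expressed as an inverse-gamma scale mixture of
#' normals). All work is done in log space; one-sided alternatives truncate
#' the Cauchy prior to a half-line.
#'
#' @param t A [t_statistic()].
#' @param prior A [prior_spec()]; `prior$c` is ignored (point null).
#' @return A `bayes_factor` object with fields `bf10`, `bf01`, `log_bf10`,
#'   `numerical_error_estimate` and a `capped` flag (log BF is capped at
#'   +/- 700).
#' @examples
#' jzs_bf_point(t_statistic(5, dof = 19, effective_n = 20),
#'              prior_spec("medium"))
#' @export
jzs_bf_point <- function(t, prior) {
  check_t_prior(t, prior)
  tv <- t$value; nu <- t$dof; n_eff <- t$effective_n; r2 <- prior$r^2

  # integrate over w in (0,1) with s = w / (1 - w)
  probe_w <- seq(1e-6, 1 - 1e-6, length.out = 257)
  log_h <- function(w) {
    s <- w / (1 - w)
    jzs_log_integrand_s(s, tv, nu, n_eff, r2) - 2 * log1p(-w)
  }
  m <- max(log_h(probe_w))
  int <- stats::integrate(function(w) exp(log_h(w) - m), 0, 1,
                          rel.tol = 1e-10, abs.tol = 1e-12,
                          subdivisions = 500L)
  log_num <- m + log(int$value)
  log_den <- -(nu + 1) / 2 * log1p(tv^2 / nu)
  log_bf <- log_num - log_den
  err <- int$abs.error / max(int$value, .Machine$double.xmin)

  if (prior$sided != "two_sided") {
    # truncated-prior marginal = 2 * full marginal * posterior half-line mass
    bounds <- if (prior$sided == "positive") c(0, Inf) else c(-Inf, 0)
    m_half <- marginal_region(tv, nu, n_eff, prior$r, bounds[1L], bounds[2L])
    m_full <- marginal_region(tv, nu, n_eff, prior$r, -Inf, Inf)
    if (m_half$value <= 0)
      return(bf_result(-LOG_BF_CAP, err, capped = TRUE))
    log_bf <- log_bf + log(2) +
      (m_half$log_scale + log(m_half$value)) -
      (m_full$log_scale + log(m_full$value))
  }
  bf_result(log_bf, err)
}

# scaled marginal likelihood integral of the data over delta in [lo, hi]
# under the (untruncated) Cauchy(0, r) prior: returns value = exp(-log_scale)
# * integral, so region masses can be compared without underflow.
# Semi-infinite regions are split at a data-adaptive edge: a finite window
# holding essentially all the likelihood-weighted mass (integrated by
# QAGS, robust to a boundary spike) plus a smooth polynomial-decay far
# tail (QAGI).
marginal_region <- function(tv, nu, n_eff, r, lo, hi) {
  log_f <- function(d)
    ldt_nc(tv, nu, d * sqrt(n_eff)) + stats::dcauchy(d, 0, r, log = TRUE)
  d_hat <- tv / sqrt(n_eff)
  lik_w <- sqrt(1 / n_eff + d_hat^2 / (2 * nu))
  edge <- abs(d_hat) + 30 * lik_w + 10 * r
  flo <- max(lo, -edge)
  fhi <- min(hi, edge)
  # breakpoints geometrically spaced around the effect estimate keep each
  # segment's dynamic range moderate even when the region boundary cuts
  # the likelihood spike
  w <- max(lik_w, r / 20)
  breaks <- sort(unique(pmin(pmax(
    c(flo, fhi, 0, d_hat + c(-64, -32, -16, -8, -4, -2, -1, -0.5, 0,
                             0.5, 1, 2, 4, 8, 16, 32, 64) * w),
    flo), fhi)))
  # scale by the maximum over the window (log_f is unimodal toward the
  # effect estimate, so the max sits at a breakpoint)
  m <- max(log_f(breaks), na.rm = TRUE)
  g <- function(d) exp(log_f(d) - m)
  value <- 0
  abs_err <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    if (b <= a) next
    if (max(log_f(c(a, (a + b) / 2, b))) - m < -40) next # negligible mass
    int <- NULL
    # quadpack can report spurious roundoff at tight tolerances; back off
    for (tol in c(1e-9, 1e-6)) {
      int <- tryCatch(
        stats::integrate(g, a, b, rel.tol = tol, abs.tol = 1e-13,
                         subdivisions = 200L),
        error = function(e) NULL)
      if (!is.null(int)) break
    }
    if (is.null(int)) {
      # last resort for a segment quadpack rejects: dense trapezoid
      d <- seq(a, b, length.out = 4001L)
      y <- g(d)
      int <- list(value = trapz(d, y),
                  abs.error = diff(range(d)) * max(y) * 1e-7)
    }
    value <- value + int$value
    abs_err <- abs_err + int$abs.error
  }
  # far Cauchy tails beyond the finite window (smooth polynomial decay)
  for (tail in list(c(lo, flo), c(fhi, hi))) {
    if (tail[1L] >= tail[2L]) next
    t_int <- tryCatch(
      stats::integrate(g, tail[1L], tail[2L], rel.tol = 1e-8,
                       abs.tol = 1e-14, subdivisions = 500L),
      error = function(e) NULL) # unresolvable tail: below roundoff anyway
    if (!is.null(t_int)) {
      value <- value + t_int$value
      abs_err <- abs_err + t_int$abs.error
    }
  }
  list(value = value, log_scale = m, abs_error = abs_err)
}

# trapezoid mass of a gridded density over a logical node selection
grid_mass <- function(x, f, keep) {
  if (!any(keep)) return(0)
  f2 <- f
  f2[!keep] <- 0
  trapz(x, f2)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Posterior density of the effect size on a grid
#'
#' Posterior of \eqn{\delta} given the t statistic under the unconstrained
#' Cauchy(r) alternative, i.e. proportional to the noncentral-t likelihood
#' \eqn{f_\nu(t \mid \delta\sqrt{n})} times the Cauchy(0, r) prior. Evaluated
#' on a symmetric grid centred on the sample effect estimate
#' \eqn{\hat d = t/\sqrt{n}} with half-width
#' \eqn{r \cdot \max(10,\ 10|t|/\sqrt{n})} (20001 points), wide enough that
#' the truncated tail mass is negligible; the returned density is normalized
#' to integrate to 1.
#'
#' @param t A [t_statistic()].
#' @param prior A [prior_spec()] (only `r` is used).
#' @param n_grid Number of grid points (odd; default 20001).
#' @return A list with `delta` (grid), `density` (normalized) and
#'   `log_norm` (log of the unnormalized marginal likelihood integral).
#' @export
delta_posterior <- function(t, prior, n_grid = 20001L) {
  check_t_prior(t, prior)
  tv <- t$value; nu <- t$dof; n_eff <- t$effective_n; r <- prior$r
  d_hat <- tv / sqrt(n_eff)
  half <- r * max(10, 10 * abs(tv) / sqrt(n_eff))
  delta <- seq(d_hat - half, d_hat + half, length.out = as.integer(n_grid))
  log_f <- ldt_nc(tv, nu, delta * sqrt(n_eff)) +
    stats::dcauchy(delta, 0, r, log = TRUE)
  m <- max(log_f)
  if (!is.finite(m))
    stop("posterior underflow: |t| too extreme for the delta grid",
         call. = FALSE)
  f <- exp(log_f - m)
  z <- trapz(delta, f)
  list(delta = delta, density = f / z, log_norm = m + log(z))
}

#' JZS Bayes factor for an interval null
#'
#' Compares two hypotheses carved out of one parent Cauchy(0, r) prior on the
#' effect size: \eqn{H_0} truncates it to the interval of trivially small
#' effects \eqn{[-c, c]}, \eqn{H_1} to its complement. The Bayes factor is
#' the ratio of posterior to prior odds of the two regions under the
#' unconstrained model,
#' \deqn{BF_{10} = \frac{P(\delta \notin [-c,c] \mid y)\,/\,P(\delta \notin
#'   [-c,c])}{P(\delta \in [-c,c] \mid y)\,/\,P(\delta \in [-c,c])},}
#' with posterior region masses from [delta_posterior()] and prior masses
#' from [cauchy_prior_mass()].
#'
#' @inheritParams jzs_bf_point
#' @param prior A [prior_spec()] with `c > 0`.
#' @return A `bayes_factor` object; `capped = TRUE` flags a posterior region
#'   mass that underflowed to 0.
#' @examples
#' jzs_bf_interval(t_statistic(2.5, dof = 9, effective_n = 10),
#'                 prior_spec("medium", c = 0.2))
#' @export
jzs_bf_interval <- function(t, prior) {
  check_t_prior(t, prior)
  if (prior$c <= 0)
    stop("interval null requires c > 0; use jzs_bf_point() for a point null",
         call. = FALSE)
  # posterior region odds from adaptive quadrature of the marginal
  # likelihood over [-c, c] and its complement; equivalent to the Bayes
  # factor between the two truncated-prior models, with exact interval
  # boundary handling at any c
  tv <- t$value; nu <- t$dof; n_eff <- t$effective_n
  m_in <- marginal_region(tv, nu, n_eff, prior$r, -prior$c, prior$c)
  m_lo <- marginal_region(tv, nu, n_eff, prior$r, -Inf, -prior$c)
  m_hi <- marginal_region(tv, nu, n_eff, prior$r, prior$c, Inf)
  scale <- max(m_in$log_scale, m_lo$log_scale, m_hi$log_scale)
  v_in <- m_in$value * exp(m_in$log_scale - scale)
  v_out <- m_lo$value * exp(m_lo$log_scale - scale) +
    m_hi$value * exp(m_hi$log_scale - scale)
  prior_in <- cauchy_prior_mass(prior$r, -prior$c, prior$c)
  prior_out <- 1 - prior_in
  if (v_in <= 0) {
    warning("posterior mass inside the interval null underflowed; ",
            "Bayes factor capped")
    return(bf_result(LOG_BF_CAP, capped = TRUE))
  }
  if (v_out <= 0) {
    warning("posterior mass outside the interval null underflowed; ",
            "Bayes factor capped")
    return(bf_result(-LOG_BF_CAP, capped = TRUE))
  }
  log_bf <- (log(v_out) - log(prior_out)) - (log(v_in) - log(prior_in))
  # approximate relative error of the region-odds ratio
  err <- m_in$abs_error / max(m_in$value, .Machine$double.xmin) +
    (m_lo$abs_error + m_hi$abs_error) /
      max(m_lo$value + m_hi$value, .Machine$double.xmin)
  bf_result(log_bf, err)
}

#' Convert a Bayes factor to posterior probabilities
#'
#' Posterior odds are BF10 times the prior odds; the posterior probabilities
#' follow as `pp_h1 = odds / (1 + odds)` and `pp_h0 = 1 - pp_h1`. With prior
#' odds 1 this is `pp_h0 = 1 / (1 + BF10)` and `pp_h1 = 1 / (1 + BF01)`.
#'
#' @param bf10 Positive Bayes factor (or a `bayes_factor` object).
#' @param prior_odds Positive prior odds P(H1)/P(H0), default 1.
#' @return A list with `pp_h0` and `pp_h1` (summing to 1).
#' @examples
#' bf_to_posterior(5) # pp_h1 = 5/6
#' @export
bf_to_posterior <- function(bf10, prior_odds = 1) {
  if (inherits(bf10, "bayes_factor")) bf10 <- bf10$bf10
  if (!is.numeric(bf10) || length(bf10) != 1L || is.na(bf10) || bf10 <= 0)
    stop("'bf10' must be a single positive number", call. = FALSE)
  if (!is.numeric(prior_odds) || length(prior_odds) != 1L ||
      is.na(prior_odds) || prior_odds <= 0)
    stop("'prior_odds' must be a single positive number", call. = FALSE)
  odds <- bf10 * prior_odds
  pp_h1 <- odds / (1 + odds)
  list(pp_h0 = 1 - pp_h1, pp_h1 = pp_h1)
}
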