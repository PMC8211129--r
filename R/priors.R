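#' Prior specification for JZS effect-size tests
#'
#' Bundles everything that determines the Bayesian model for a t-design:
#' the Cauchy scale `r` placed on the standardized effect size
#' \eqn{\delta = (\mu_1 - \mu_2)/\sigma}, the half-width `c` of the interval
#' null \eqn{|\delta| \le c} (0 means a point null), the prior odds
#' \eqn{P(H_1)/P(H_0)}, and the sidedness of the alternative.
#'
#' The named scales follow the usual default-Bayes-factor conventions:
#' `"medium"` = \eqn{\sqrt{2}/2}, `"wide"` = 1, `"ultrawide"` = \eqn{\sqrt{2}}.
#' Half of the Cauchy prior mass lies inside \eqn{[-r, r]}.
#'
#' @param r Cauchy scale on delta; a positive number or one of `"medium"`,
#'   `"wide"`, `"ultrawide"`.
#' @param c Half-width of the interval of trivially small effects
#'   (non-negative; 0 selects a point null).
#' @param prior_odds Prior odds P(H1)/P(H0), positive (default 1).
#' @param sided One of `"two_sided"`, `"positive"`, `"negative"`.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec("medium", c = 0.2)
#' @export
prior_spec <- function(r = "medium", c = 0, prior_odds = 1,
                       sided = c("two_sided", "positive", "negative")) {
  r <- prior_scale(r)
  sided <- match.arg(sided)
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0)
    stop("'c' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(prior_odds) || length(prior_odds) != 1L ||
      !is.finite(prior_odds) || prior_odds <= 0)
    stop("'prior_odds' must be a single positive number", call. = FALSE)
  structure(
    list(r = r, c = as.numeric(c), prior_odds = as.numeric(prior_odds),
         sided = sided),
    class = "prior_spec")
}

#' Resolve a Cauchy prior-scale label
#'
#' @param r A positive number, or `"medium"` (\eqn{\sqrt 2/2}), `"wide"` (1)
#'   or `"ultrawide"` (\eqn{\sqrt 2}).
#' @return The numeric scale.
#' @export
prior_scale <- function(r) {
  if (is.character(r)) {
    r <- match.arg(r, c("medium", "wide", "ultrawide"))
    r <- switch(r, medium = sqrt(2) / 2, wide = 1, ultrawide = sqrt(2))
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("Cauchy scale 'r' must be a positive number or one of ",
         "'medium', 'wide', 'ultrawide'", call. = FALSE)
  as.numeric(r)
}

#' @export
print.prior_spec <- function(x, ...) {
  null_desc <- if (x$c > 0)
    sprintf("interval null |delta| <= %g", x$c) else "point null delta = 0"
  cat(sprintf("JZS prior: delta ~ Cauchy(0, %.4f), %s, prior odds %g, %s\n",
              x$r, null_desc, x$prior_odds, x$sided))
  invisible(x)
}

#' Central Cauchy interval probability
#'
#' Probability that the effect size falls in `[a, b]` under the Cauchy(0, r)
#' prior, in closed form via the arctangent CDF. By construction half of the
#' mass lies between -r and +r.
#'
#' @param r Positive Cauchy scale.
#' @param a,b Interval endpoints, `a <= b` (infinite endpoints allowed).
#' @return `P(a <= delta <= b)`.
#' @examples
#' cauchy_prior_mass(1, -1, 1) # 0.5
#' @export
cauchy_prior_mass <- function(r, a, b) {
  r <- prior_scale(r)
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b) || a > b)
    stop("'a' and 'b' must be numbers with a <= b", call. = FALSE)
  stats::pcauchy(b, 0, r) - stats::pcauchy(a, 0, r)
}
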