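#' Plot a classical SPM{t} result
#'
#' Draws the t field over percent of movement time with the two-tailed
#' critical thresholds and shades supra-threshold clusters.
#'
#' @param x An [spm_t_test()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spm_t <- function(x, ...) {
  pct <- node_to_pct(seq_len(x$Q), x$Q)
  graphics::plot(pct, x$t_field, type = "l", xlab = "movement time (%)",
                 ylab = "SPM{t}", ...)
  graphics::abline(h = c(-x$t_star, x$t_star), lty = 2)
  graphics::abline(h = 0, col = "grey")
  if (nrow(x$clusters) > 0L)
    for (i in seq_len(nrow(x$clusters)))
      graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3L],
                     x$clusters$end_pct[i], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
  invisible(x)
}

#' Plot a posterior probability map
#'
#' Draws PP(H1) over percent of movement time with the 0.05 / 0.95
#' posterior-probability thresholds, and marks nodes admitted by the
#' q-value rule for either hypothesis.
#'
#' @param x A [bayesian_spm()] result.
#' @param q_threshold q-value threshold to mark (default 0.05).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ppm <- function(x, q_threshold = 0.05, ...) {
  pct <- node_to_pct(seq_len(x$Q), x$Q)
  graphics::plot(pct, x$pp_h1, type = "l", ylim = c(0, 1),
                 xlab = "movement time (%)", ylab = "P(H1 | data)", ...)
  graphics::abline(h = c(0.05, 0.95), lty = 2)
  sel1 <- x$q_h1 <= q_threshold
  sel0 <- x$q_h0 <= q_threshold
  if (any(sel1)) graphics::points(pct[sel1], x$pp_h1[sel1], pch = 16,
                                  col = "red", cex = 0.5)
  if (any(sel0)) graphics::points(pct[sel0], x$pp_h1[sel0], pch = 16,
                                  col = "blue", cex = 0.5)
  invisible(x)
}
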