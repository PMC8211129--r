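#' Bayesian SPM: a posterior probability map over the field
#'
#' Runs the JZS Bayes-factor t test ([jzs_bf_point()] or
#' [jzs_bf_interval()]) at every node of the field, converts each Bayes
#' factor to posterior probabilities via [bf_to_posterior()], and attaches
#' posterior error probabilities (PEP = 1 - PP of the claimed hypothesis)
#' and q-values per hypothesis.
#'
#' @param a,b [trajectory_set()] objects.
#' @param design `"paired"` or `"two_sample"`.
#' @param prior A [prior_spec()].
#' @param null_type `"point"` or `"interval"`; `"interval"` requires
#'   `prior$c > 0`.
#' @return An object of class `ppm` with length-Q fields `bf10`, `pp_h1`,
#'   `pp_h0`, `pep_h1`, `pep_h0`, `q_h1`, `q_h0`, the t field `t`, plus
#'   `prior`, `design`, `null_type`, `dof`, `effective_n`, `Q`.
#' @examples
#' set.seed(1)
#' g <- make_two_local_max(seed = 1)
#' ppm <- bayesian_spm(g$group1, g$group2, "two_sample",
#'                     prior_spec("medium", c = 0.2), "interval")
#' @export
bayesian_spm <- function(a, b, design = c("paired", "two_sample"),
                         prior = prior_spec("medium", c = 0.2),
                         null_type = c("interval", "point")) {
  design <- match.arg(design)
  null_type <- match.arg(null_type)
  if (!inherits(prior, "prior_spec"))
    stop("'prior' must be a prior_spec object", call. = FALSE)
  tf <- t_statistic_field(a, b, design)
  bf_fun <- if (null_type == "point") jzs_bf_point else jzs_bf_interval
  log_bf10 <- vapply(tf$t, function(tv) {
    bf_fun(t_statistic(tv, tf$dof, tf$effective_n), prior)$log_bf10
  }, numeric(1L))
  odds <- exp(log_bf10) * prior$prior_odds
  pp_h1 <- odds / (1 + odds)
  pp_h0 <- 1 - pp_h1
  pep_h1 <- pp_h0   # error probability of claiming H1
  pep_h0 <- pp_h1
  structure(
    list(bf10 = exp(log_bf10), log_bf10 = log_bf10,
         pp_h1 = pp_h1, pp_h0 = pp_h0,
         pep_h1 = pep_h1, pep_h0 = pep_h0,
         q_h1 = q_values(pep_h1), q_h0 = q_values(pep_h0),
         t = tf$t, dof = tf$dof, effective_n = tf$effective_n, Q = tf$Q,
         prior = prior, design = design, null_type = null_type),
    class = "ppm")
}

#' @export
print.ppm <- function(x, ...) {
  cat(sprintf(
    "Bayesian SPM (%s design, %s null, r = %.4f%s): Q = %d nodes\n",
    x$design, x$null_type, x$prior$r,
    if (x$null_type == "interval") sprintf(", c = %g", x$prior$c) else "",
    x$Q))
  cat(sprintf("  max PP(H1) = %.3f, max PP(H0) = %.3f\n",
              max(x$pp_h1), max(x$pp_h0)))
  for (h in c("H1", "H0")) {
    cl <- extract_clusters(x, h, "q_005")
    cat(sprintf("  %s clusters (q <= 0.05): %s\n", h,
                if (nrow(cl) == 0) "none" else
                  paste(sprintf("%d-%d", cl$start_node, cl$end_node),
                        collapse = ", ")))
  }
  invisible(x)
}

#' q-values from posterior error probabilities
#'
#' The q-value of a node is the cumulative mean of the PEPs no larger than
#' its own: sort PEPs ascending, take running means, and map back to the
#' original node order. It is the minimal FDR threshold at which the node
#' enters a discovery set. Tied PEPs all receive the running mean at the
#' last tied rank, which makes the result independent of how the sort
#' breaks ties.
#'
#' @param pep Numeric vector of posterior error probabilities in \[0, 1\].
#' @return q-values in the original node order.
#' @examples
#' q_values(c(0.01, 0.02, 0.06)) # 0.01 0.015 0.03
#' @export
q_values <- function(pep) {
  if (!is.numeric(pep) || anyNA(pep) || any(pep < 0 | pep > 1))
    stop("'pep' must be probabilities in [0, 1]", call. = FALSE)
  o <- order(pep)
  cm <- cumsum(pep[o]) / seq_along(pep)
  # ties share the cumulative mean at their last tied rank
  last_of_tie <- rev(!duplicated(rev(pep[o])))
  cm_tied <- cm
  cm_tied[!last_of_tie] <- NA_real_
  # carry the last-tied value backwards over each tie block
  for (i in rev(seq_along(cm_tied)[-length(cm_tied)]))
    if (is.na(cm_tied[i])) cm_tied[i] <- cm_tied[i + 1L]
  q <- numeric(length(pep))
  q[o] <- cm_tied
  q
}

#' Supra-threshold clusters of a posterior probability map
#'
#' Finds maximal contiguous runs of nodes where the requested hypothesis
#' passes the chosen rule: posterior probability at least `pp_threshold`
#' (`rule = "pp_095"`) or q-value at most `q_threshold` (`rule = "q_005"`).
#' Node ranges are reported 1-based inclusive together with percent of
#' movement time. For the q rule the attribute `max_pep_admitted` records
#' the largest PEP among admitted nodes (the effective pointwise threshold).
#'
#' @param map A [bayesian_spm()] result.
#' @param hypothesis `"H1"` or `"H0"`.
#' @param rule `"pp_095"` or `"q_005"`.
#' @param pp_threshold Posterior-probability threshold (default 0.95).
#' @param q_threshold q-value threshold (default 0.05).
#' @return A data frame with columns `hypothesis`, `rule`, `start_node`,
#'   `end_node`, `start_pct`, `end_pct`, `extremum` (max PP for the pp rule,
#'   min q for the q rule); zero rows when nothing passes.
#' @export
extract_clusters <- function(map, hypothesis = c("H1", "H0"),
                             rule = c("pp_095", "q_005"),
                             pp_threshold = 0.95, q_threshold = 0.05) {
  hypothesis <- match.arg(hypothesis)
  rule <- match.arg(rule)
  if (!inherits(map, "ppm"))
    stop("'map' must be a ppm object", call. = FALSE)
  pp <- if (hypothesis == "H1") map$pp_h1 else map$pp_h0
  qv <- if (hypothesis == "H1") map$q_h1 else map$q_h0
  pep <- if (hypothesis == "H1") map$pep_h1 else map$pep_h0
  pass <- if (rule == "pp_095") pp >= pp_threshold else qv <= q_threshold
  runs <- passing_runs(pass)
  ex <- vapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    if (rule == "pp_095") max(pp[idx]) else min(qv[idx])
  }, numeric(1L))
  out <- data.frame(
    hypothesis = rep(hypothesis, nrow(runs)),
    rule = rep(rule, nrow(runs)),
    start_node = runs$start, end_node = runs$end,
    start_pct = node_to_pct(runs$start, map$Q),
    end_pct = node_to_pct(runs$end, map$Q),
    extremum = ex,
    stringsAsFactors = FALSE)
  if (rule == "q_005")
    attr(out, "max_pep_admitted") <-
      if (any(pass)) max(pep[pass]) else NA_real_
  out
}

# maximal runs of TRUE, as start/end data frame (possibly 0 rows)
passing_runs <- function(pass) {
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Cluster table for a full analysis
#'
#' Assembles the Bayesian cluster table across both hypotheses and both
#' thresholding rules, in the fixed CSV schema used by [run_analysis()].
#'
#' @param map A [bayesian_spm()] result.
#' @param dataset Text label for the `dataset` column.
#' @param r_label Text label for the prior scale column (e.g. `"medium"`).
#' @return Data frame with columns `dataset`, `design`, `null_type`,
#'   `r_label`, `hypothesis`, `rule`, `start_node`, `end_node`,
#'   `start_pct`, `end_pct`, `extremum`.
#' @export
ppm_cluster_table <- function(map, dataset = "", r_label = "") {
  parts <- list()
  for (h in c("H0", "H1"))
    for (rl in c("pp_095", "q_005"))
      parts[[paste(h, rl)]] <- extract_clusters(map, h, rl)
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  if (nrow(tab) == 0)
    tab <- tab[, , drop = FALSE]
  cbind(data.frame(dataset = rep(dataset, nrow(tab)),
                   design = rep(map$design, nrow(tab)),
                   null_type = rep(map$null_type, nrow(tab)),
                   r_label = rep(r_label, nrow(tab)),
                   stringsAsFactors = FALSE),
        tab)
}
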