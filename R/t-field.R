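#' Nodewise t statistics over the field
#'
#' Computes the t statistic independently at every node: a paired t test on
#' the trial-wise differences (`dof = J - 1`, effective n = J), or a
#' pooled-variance two-sample t test (`dof = n1 + n2 - 2`, effective
#' n = n1*n2/(n1+n2)).
#'
#' @param a,b [trajectory_set()] objects. Paired designs need equal J and Q;
#'   two-sample designs need equal Q.
#' @param design `"paired"` or `"two_sample"`.
#' @return A list with `t` (length-Q statistic field), `dof`, `effective_n`
#'   and `Q`.
#' @export
t_statistic_field <- function(a, b, design = c("paired", "two_sample")) {
  design <- match.arg(design)
  if (!inherits(a, "trajectory_set") || !inherits(b, "trajectory_set"))
    stop("'a' and 'b' must be trajectory_set objects", call. = FALSE)
  if (a$Q != b$Q)
    stop("node counts differ: Q = ", a$Q, " vs ", b$Q, call. = FALSE)
  if (design == "paired") {
    if (a$J != b$J)
      stop("paired design needs equal trial counts (J = ", a$J, " vs ",
           b$J, ")", call. = FALSE)
    if (a$J < 2L) stop("paired design needs J >= 2 trials", call. = FALSE)
    d <- a$values - b$values
    mu <- colMeans(d)
    v <- apply(d, 2L, stats::var)
    check_degenerate(v)
    tval <- mu / sqrt(v / a$J)
    list(t = tval, dof = a$J - 1, effective_n = a$J, Q = a$Q)
  } else {
    if (a$J < 2L || b$J < 2L)
      stop("two-sample design needs >= 2 trials per group", call. = FALSE)
    n1 <- a$J; n2 <- b$J
    v1 <- apply(a$values, 2L, stats::var)
    v2 <- apply(b$values, 2L, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    check_degenerate(sp2)
    tval <- (colMeans(a$values) - colMeans(b$values)) /
      sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = tval, dof = n1 + n2 - 2, effective_n = n1 * n2 / (n1 + n2),
         Q = a$Q)
  }
}

check_degenerate <- function(v) {
  bad <- which(v <= 0)
  if (length(bad) > 0L)
    stop("zero residual variance at node ", bad[1L],
         ": t statistic undefined there", call. = FALSE)
  invisible(NULL)
}
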