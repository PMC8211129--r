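#' A set of registered 1D trials
#'
#' Wraps a J x Q numeric matrix of time-normalized trials: rows are
#' trials/subjects, columns are the Q field nodes (typically 101, i.e.
#' 0-100% of movement time).
#'
#' @param values Numeric matrix (or object coercible to one), J x Q, no
#'   missing values, Q >= 3.
#' @param label Optional text label for the set.
#' @return An object of class `trajectory_set`.
#' @examples
#' trajectory_set(matrix(rnorm(5 * 101), 5, 101), label = "demo")
#' @export
trajectory_set <- function(values, label = "") {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("trajectory values must be numeric", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("trajectory values must be finite with no missing entries",
         call. = FALSE)
  if (ncol(values) < 3L)
    stop("a trajectory set needs at least Q = 3 nodes", call. = FALSE)
  if (nrow(values) < 1L)
    stop("a trajectory set needs at least one trial", call. = FALSE)
  dimnames(values) <- NULL
  structure(list(values = values, label = as.character(label)[1L],
                 J = nrow(values), Q = ncol(values)),
            class = "trajectory_set")
}

#' @export
as.matrix.trajectory_set <- function(x, ...) x$values

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set%s: J = %d trials x Q = %d nodes\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$J, x$Q))
  invisible(x)
}

#' Percent of movement time for a node index
#'
#' Nodes are 1-based; node 1 maps to 0% and node Q to 100%, i.e.
#' `pct = 100 * (node - 1) / (Q - 1)`.
#'
#' @param node Integer node index (vectorized).
#' @param Q Number of nodes in the field.
#' @return Percent of movement time.
#' @export
node_to_pct <- function(node, Q) 100 * (node - 1) / (Q - 1)

#' Read a trajectory matrix from a delimited text file
#'
#' Expects a rectangular numeric table, rows = trials and columns = nodes,
#' with an optional header row of node labels. Ragged rows, non-numeric
#' cells and missing values are rejected with the offending row and column.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default `","`).
#' @param label Label for the resulting set (default: the file name).
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path, delimiter = ",", label = basename(path)) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = delimiter, blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged table in '%s': row %d has %d fields, expected %d",
                 path, which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L]),
         call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character",
                           blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  header <- suppressWarnings(any(is.na(as.numeric(unlist(raw[1L, ])))))
  if (header) raw <- raw[-1L, , drop = FALSE]
  num <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw)), USE.NAMES = FALSE))
  num <- matrix(num, nrow = nrow(raw))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-numeric or missing value in '%s' at data row %d, column %d",
      path, bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  ts <- trajectory_set(num, label = label)
  message(sprintf("read '%s': J = %d trials, Q = %d nodes", path, ts$J, ts$Q))
  ts
}

#' Write a trajectory set to a delimited text file
#'
#' Inverse of [read_trajectories()] (no header row); a write/read round
#' trip reproduces the values bitwise via full-precision formatting.
#'
#' @param x A [trajectory_set()] or numeric matrix.
#' @param path Output file path.
#' @param delimiter Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path, delimiter = ",") {
  m <- if (inherits(x, "trajectory_set")) x$values else as.matrix(x)
  lines <- apply(m, 1L, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = delimiter))
  writeLines(lines, path)
  invisible(path)
}
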