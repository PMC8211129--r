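# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Q x Q smoothing operator: truncated Gaussian kernel columns scaled to
# unit L2 norm, so white noise times the operator has exactly unit variance
# at every node, including the field ends
smoothing_operator <- function(Q, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma))
  K <- matrix(0, Q, Q)
  for (q in seq_len(Q)) {
    p <- max(1L, q - half):min(Q, q + half)
    w <- exp(-(p - q)^2 / (2 * sigma^2))
    K[p, q] <- w / sqrt(sum(w^2))
  }
  K
}

#' Smooth unit-variance Gaussian random trajectories
#'
#' White Gaussian noise convolved along the node axis with a Gaussian
#' kernel of the requested FWHM (truncated at 4 standard deviations), then
#' scaled so every node — including the field endpoints — has exactly unit
#' variance in expectation, and finally multiplied by `amplitude_sd`.
#'
#' @param J Number of trials (>= 2).
#' @param Q Number of field nodes (default 101).
#' @param fwhm Smoothness of the fields in nodes (default 20).
#' @param amplitude_sd Pointwise standard deviation (default 1).
#' @param seed Optional integer seed for reproducibility.
#' @param label Label for the resulting set.
#' @return A [trajectory_set()].
#' @examples
#' y <- smooth_gaussian_fields(J = 6, fwhm = 10, seed = 1)
#' @export
smooth_gaussian_fields <- function(J, Q = 101L, fwhm = 20, amplitude_sd = 1,
                                   seed = NULL, label = "smooth fields") {
  if (J < 2L) stop("'J' must be >= 2", call. = FALSE)
  if (Q < 3L) stop("'Q' must be >= 3", call. = FALSE)
  if (fwhm <= 0) stop("'fwhm' must be positive", call. = FALSE)
  if (fwhm >= Q)
    warning("fwhm >= Q: fields will be nearly constant along the nodes")
  K <- smoothing_operator(Q, fwhm)
  z <- with_seed(seed, matrix(stats::rnorm(J * Q), J, Q))
  trajectory_set(amplitude_sd * (z %*% K), label = label)
}

#' Gaussian pulse over the field
#'
#' A length-Q curve `amplitude * exp(-(q - centre)^2 / (2 sigma^2))` with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`; the building block for burst effects
#' and asymmetry pulses.
#'
#' @param Q Number of field nodes.
#' @param centre_node Pulse centre (node units; may be fractional).
#' @param amplitude Peak height.
#' @param fwhm Pulse full width at half maximum, in nodes.
#' @return Numeric vector of length Q.
#' @export
gaussian_pulse <- function(Q, centre_node, amplitude, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * exp(-((seq_len(Q) - centre_node)^2) / (2 * sigma^2))
}

#' Two-group example data with two local mean bursts
#'
#' Emulates the classic two-local-maximum example: group 1 consists of
#' smooth unit Gaussian trajectories; group 2 adds Gaussian-pulse mean
#' offsets centred at 25% and 75% of movement time. Burst geometry defaults
#' (amplitude 2.8 effect-size units, pulse FWHM 10 nodes) are tuning chosen
#' so that with 2 x n = 6 trials the classical SPM detects clusters near
#' both bursts in a majority of random seeds.
#'
#' @param n_per_group Trials per group (default 6).
#' @param Q Nodes (default 101).
#' @param burst_pct Burst centres in percent of movement time
#'   (default `c(25, 75)`).
#' @param burst_amplitude Peak height of each burst in units of the noise
#'   SD (default 2.8).
#' @param burst_fwhm Pulse width in nodes (default 10).
#' @param noise_fwhm Smoothness of the background fields (default 20).
#' @param seed Optional integer seed.
#' @return A list with `group1` and `group2` [trajectory_set()]s.
#' @examples
#' g <- make_two_local_max(seed = 1)
#' @export
make_two_local_max <- function(n_per_group = 6L, Q = 101L,
                               burst_pct = c(25, 75),
                               burst_amplitude = 2.8, burst_fwhm = 10,
                               noise_fwhm = 20, seed = NULL) {
  if (any(burst_pct < 0 | burst_pct > 100))
    stop("'burst_pct' must lie in [0, 100]", call. = FALSE)
  centre_nodes <- 1 + burst_pct * (Q - 1) / 100
  effect <- Reduce(`+`, lapply(centre_nodes, function(cn)
    gaussian_pulse(Q, cn, burst_amplitude, burst_fwhm)))
  with_seed(seed, {
    g1 <- smooth_gaussian_fields(n_per_group, Q, noise_fwhm,
                                 label = "two-local-max group 1")
    g2 <- smooth_gaussian_fields(n_per_group, Q, noise_fwhm,
                                 label = "two-local-max group 2")
    g2 <- trajectory_set(sweep(g2$values, 2L, effect, "+"), label = g2$label)
    list(group1 = g1, group2 = g2, effect = effect)
  })
}

#' Synthetic gait-like paired data (left vs right knee flexion)
#'
#' Synthetic stand-in for a single-subject gait-symmetry experiment: both
#' "legs" share a smooth periodic knee-flexion-like baseline (two Gaussian
#' bumps emulating the stance and swing flexion peaks, in degrees); the
#' second leg is offset by a Gaussian-pulse asymmetry of peak height
#' `asymmetry_deg` centred late in the cycle; cycle-to-cycle noise consists
#' of smooth unit fields scaled by `within_sd`.
#'
#' @param n_cycles Number of gait cycles per leg (>= 2).
#' @param asymmetry_deg Peak left-right mean difference in degrees
#'   (default 0 = perfectly symmetric).
#' @param within_sd Within-subject cycle-to-cycle SD in degrees
#'   (default 2.5, a typical treadmill value).
#' @param Q Nodes (default 101).
#' @param asymmetry_pct Centre of the asymmetry pulse in percent of the
#'   cycle (default 76).
#' @param asymmetry_fwhm Width of the asymmetry pulse in nodes (default 10).
#' @param noise_fwhm Smoothness of the trial noise (default 20).
#' @param seed Optional integer seed.
#' @return A list with `left` and `right` [trajectory_set()]s and the
#'   `baseline` and `asymmetry` mean curves.
#' @examples
#' g <- make_gait_like(n_cycles = 20, asymmetry_deg = 2, seed = 1)
#' @export
make_gait_like <- function(n_cycles = 99L, asymmetry_deg = 0,
                           within_sd = 2.5, Q = 101L, asymmetry_pct = 76,
                           asymmetry_fwhm = 10, noise_fwhm = 20,
                           seed = NULL) {
  if (n_cycles < 2L) stop("'n_cycles' must be >= 2", call. = FALSE)
  pct <- node_to_pct(seq_len(Q), Q)
  baseline <- 18 * exp(-((pct - 15)^2) / (2 * 8^2)) +
    62 * exp(-((pct - 72)^2) / (2 * 11^2))
  asym_node <- 1 + asymmetry_pct * (Q - 1) / 100
  asymmetry <- gaussian_pulse(Q, asym_node, asymmetry_deg, asymmetry_fwhm)
  with_seed(seed, {
    nl <- smooth_gaussian_fields(n_cycles, Q, noise_fwhm)
    nr <- smooth_gaussian_fields(n_cycles, Q, noise_fwhm)
    left <- sweep(within_sd * nl$values, 2L, baseline, "+")
    right <- sweep(within_sd * nr$values, 2L, baseline + asymmetry, "+")
    list(left = trajectory_set(left, "left knee flexion (deg)"),
         right = trajectory_set(right, "right knee flexion (deg)"),
         baseline = baseline, asymmetry = asymmetry)
  })
}

#' Specify a continuum model for power analysis
#'
#' A continuum model is a mean curve plus smooth Gaussian noise: trials are
#' `baseline + effect + noise_sd * smooth unit fields`.
#'
#' @param baseline Length-Q mean curve (units of the measured variable).
#' @param effect Length-Q effect curve added on top (default all zero).
#' @param noise_fwhm Noise smoothness in nodes (default 20).
#' @param noise_sd Pointwise noise SD (default 1).
#' @return An object of class `continuum_model`.
#' @export
continuum_model <- function(baseline, effect = numeric(length(baseline)),
                            noise_fwhm = 20, noise_sd = 1) {
  if (length(effect) != length(baseline))
    stop("'baseline' and 'effect' must have the same length", call. = FALSE)
  if (length(baseline) < 3L) stop("need Q >= 3 nodes", call. = FALSE)
  structure(list(baseline = as.numeric(baseline),
                 effect = as.numeric(effect),
                 noise_fwhm = noise_fwhm, noise_sd = noise_sd,
                 Q = length(baseline)),
            class = "continuum_model")
}

sample_model <- function(model, n) {
  noise <- smooth_gaussian_fields(n, model$Q, model$noise_fwhm)
  trajectory_set(sweep(model$noise_sd * noise$values, 2L,
                       model$baseline + model$effect, "+"))
}

#' Simulation-based continuum power analysis
#'
#' Omnibus power of the classical paired SPM{t} test for a range of sample
#' sizes: at each n, `iterations` paired datasets are drawn (condition A
#' from the null model, condition B from the alternative model) and power
#' is the fraction of datasets with at least one supra-threshold cluster
#' anywhere along the continuum. With `alt_model = null_model` the curve
#' estimates the field-wide false positive rate, which should sit near
#' `alpha`.
#'
#' @param null_model,alt_model [continuum_model()] objects sharing Q.
#' @param n_values Integer sample sizes to evaluate.
#' @param alpha Field-wide Type I error rate (default 0.05).
#' @param iterations Simulated datasets per n (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `power_curve`: a data frame with columns `n`
#'   and `power`, plus attributes `alpha`, `iterations`, `seed`.
#' @examples
#' m0 <- continuum_model(rep(0, 101))
#' m1 <- continuum_model(rep(0, 101),
#'                       effect = gaussian_pulse(101, 77, 2, 10),
#'                       noise_sd = 2.5)
#' pw <- continuum_power(m0, m1, n_values = c(10, 40), iterations = 50,
#'                       seed = 1)
#' @export
continuum_power <- function(null_model, alt_model, n_values,
                            alpha = 0.05, iterations = 1000L, seed = NULL) {
  if (!inherits(null_model, "continuum_model") ||
      !inherits(alt_model, "continuum_model"))
    stop("models must be continuum_model objects", call. = FALSE)
  if (null_model$Q != alt_model$Q)
    stop("null and alternative models must share Q", call. = FALSE)
  n_values <- sort(as.integer(n_values))
  if (any(n_values < 2L)) stop("all sample sizes must be >= 2", call. = FALSE)
  power <- with_seed(seed, vapply(n_values, function(n) {
    hits <- vapply(seq_len(iterations), function(i) {
      a <- sample_model(null_model, n)
      b <- sample_model(alt_model, n)
      nrow(spm_t_test(a, b, "paired", alpha = alpha)$clusters) > 0L
    }, logical(1L))
    mean(hits)
  }, numeric(1L)))
  structure(data.frame(n = n_values, power = power),
            class = c("power_curve", "data.frame"),
            alpha = alpha, iterations = as.integer(iterations),
            seed = seed)
}

#' Smallest sample size reaching a power target
#'
#' @param curve A [continuum_power()] result.
#' @param target Power target (default 0.80).
#' @return The smallest evaluated n with power >= target, or `NA` if the
#'   target is never reached.
#' @export
minimum_n <- function(curve, target = 0.80) {
  hit <- which(curve$power >= target)
  if (length(hit) == 0L) return(NA_integer_)
  curve$n[min(hit)]
}
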