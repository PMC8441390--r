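# Population statistics used for expression-trace summaries.

#' Running mean over a sliding time window
#'
#' Mean of all values whose time lies within half a window of each query
#' time; a mean is emitted only where at least `min_points` observations fall
#' in the window (sparse output is expected near gaps).
#'
#' @param time,value Observation times (min) and values (unordered allowed).
#' @param window Window width in minutes (default 1).
#' @param min_points Minimum observations required to emit a mean (default 9).
#' @param query_times Times at which to evaluate; default the sorted unique
#'   observation times.
#' @return Time series data.frame (`time`, `value`) containing only emitted
#'   points.
#' @export
running_mean <- function(time, value, window = 1, min_points = 9,
                         query_times = NULL) {
  stopifnot(window > 0, length(time) == length(value))
  if (is.null(query_times)) query_times <- sort(unique(time))
  res <- vapply(query_times, function(q) {
    sel <- abs(time - q) <= window / 2
    if (sum(sel) >= min_points) mean(value[sel]) else NA_real_
  }, numeric(1))
  out <- time_series(query_times, res)
  out[is.finite(out$value), , drop = FALSE]
}

#' Normal-theory confidence interval at a time point
#'
#' Interval centred on the sample mean with half-width
#' `z * sd / sqrt(n)`; returned only when at least `min_samples` samples are
#' available, otherwise `NULL`.
#'
#' @param samples Numeric vector of observations at one time point.
#' @param level Confidence level in (0, 1).
#' @param min_samples Minimum number of samples required (default 5).
#' @return `c(lower, upper)` or `NULL`.
#' @export
normal_ci <- function(samples, level = 0.95, min_samples = 5) {
  stopifnot(level > 0, level < 1)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < min_samples) return(NULL)
  m <- mean(samples)
  half <- qnorm((1 + level) / 2) * sd(samples) / sqrt(n)
  c(lower = m - half, upper = m + half)
}

# Second-order finite-difference gradient on a possibly non-uniform grid
# (one-sided at the edges); exact for linear data.
fd_gradient <- function(time, value) {
  n <- length(time)
  if (n < 2) stop("gradient needs at least 2 points")
  g <- numeric(n)
  g[1] <- (value[2] - value[1]) / (time[2] - time[1])
  g[n] <- (value[n] - value[n - 1]) / (time[n] - time[n - 1])
  if (n > 2) {
    hs <- time[2:(n - 1)] - time[1:(n - 2)]
    hd <- time[3:n] - time[2:(n - 1)]
    g[2:(n - 1)] <- (hs^2 * value[3:n] + (hd^2 - hs^2) * value[2:(n - 1)] -
                       hd^2 * value[1:(n - 2)]) / (hs * hd * (hd + hs))
  }
  g
}

#' Activation rate of an expression count curve
#'
#' Slope of the activation curve at its steepest point early during
#' activation: the maximum of the finite-difference gradient of the series
#' restricted to the window (default 0-7 min).
#'
#' @param time,value The count (or intensity) series.
#' @param window Inclusive time window in minutes.
#' @return Maximum slope (value units per minute).
#' @export
activation_rate <- function(time, value, window = c(0, 7)) {
  o <- order(time)
  time <- time[o]; value <- value[o]
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 3) stop("need at least 3 points in the activation window")
  max(fd_gradient(time[sel], value[sel]))
}
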