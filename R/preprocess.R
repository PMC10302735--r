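# Signal path: zero-phase Butterworth low-pass, acceleration by central
# second differences, 3D -> 1D magnitude.

#' Zero-phase low-pass Butterworth filter
#'
#' Filters every axis of every channel with a second-order Butterworth
#' design applied forward-backward (zero phase). The cutoff is honoured as
#' the single-pass -3 dB point, so the two-pass amplitude gain at the cutoff
#' frequency is 1/2.
#'
#' @param trial A [motion_trial()].
#' @param cutoff Cutoff frequency in Hz; must lie strictly below Nyquist.
#' @return The trial with filtered channels and `filter` metadata attached
#'   (order 2, cutoff, zero-phase flag).
#' @export
butterworth_lowpass <- function(trial, cutoff) {
  validate_motion_trial(trial)
  fs <- trial$sampling_rate
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop(sprintf("cutoff must lie in (0, %g) Hz", fs / 2), call. = FALSE)
  if (n_samples(trial) < 6L)
    stop("series too short to filter (need >= 3x filter order)",
         call. = FALSE)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  trial$channels <- lapply(trial$channels, function(m) {
    out <- apply(m, 2L, function(x) signal::filtfilt(bf, x))
    dimnames(out) <- dimnames(m)
    out
  })
  trial$filter <- list(order = 2L, cutoff_hz = cutoff, zero_phase = TRUE)
  trial
}

#' Linear acceleration from position
#'
#' Central second finite difference per axis, scaled by the squared sampling
#' rate; endpoints use one-sided second differences so the length is
#' preserved. Exact for quadratic trajectories.
#'
#' @param trial A (typically filtered) [motion_trial()].
#' @return Named list of `T x 3` acceleration matrices (mm/s^2), one per
#'   channel.
#' @export
derive_acceleration <- function(trial) {
  fs2 <- trial$sampling_rate^2
  lapply(trial$channels, function(m) {
    out <- apply(m, 2L, second_difference)
    dimnames(out) <- dimnames(m)
    out * fs2
  })
}

second_difference <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- c(x[3L] - 2 * x[2L] + x[1L],
         x[-c(1L, 2L)] - 2 * x[-c(1L, n)] + x[-c(n - 1L, n)],
         x[n] - 2 * x[n - 1L] + x[n - 2L])
  d
}

#' Per-sample 3D magnitude
#'
#' Collapses a 3D series to one nonnegative value per time step via the
#' Euclidean norm sqrt(X^2 + Y^2 + Z^2), making the result independent of
#' sensor orientation (invariant to any rotation of the axes).
#'
#' @param xyz A `T x 3` numeric matrix.
#' @param sampling_rate Hz, carried along for downstream spectral analysis.
#' @return A `scalar_series` list with `values`, `kind` and `sampling_rate`.
#' @export
magnitude_1d <- function(xyz, sampling_rate = NA_real_) {
  if (any(!is.finite(xyz))) stop("non-finite values in 3D series",
                                 call. = FALSE)
  structure(list(values = sqrt(rowSums(xyz^2)),
                 kind = "accel_magnitude",
                 sampling_rate = sampling_rate),
            class = "scalar_series")
}
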