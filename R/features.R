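# Frequency-domain feature construction.

#' Two-sided DFT magnitude of a mean-removed series
#'
#' Helper underlying [frequency_features()]; exposed because its Parseval
#' identity (sum of squared magnitudes over the full spectrum equals N times
#' the time-domain energy) is a useful self-check.
#'
#' @param x Numeric series.
#' @return Vector of `length(x)` DFT magnitudes of `x - mean(x)`.
#' @export
dft_magnitude <- function(x) Mod(stats::fft(x - mean(x)))

#' Fixed-length spectral feature vector
#'
#' Magnitude of the one-sided DFT of the mean-removed series, interpolated
#' onto `n_bins` equally spaced normalized frequencies in (0, 0.5] cycles
#' per sample, then scaled to unit Euclidean norm. The fixed-length summary
#' makes trials of unequal duration comparable; removing the mean discards
#' the arbitrary spatial origin. A constant series yields the zero vector
#' (the normalization guard).
#'
#' @param x Numeric series, `length(x) >= n_bins`.
#' @param n_bins Number of spectral bins (>= 2).
#' @return Nonnegative numeric vector of length `n_bins` with unit norm
#'   (or all zeros for a constant input).
#' @export
frequency_features <- function(x, n_bins = 16L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  n <- length(x)
  if (n < n_bins) stop("series shorter than n_bins", call. = FALSE)
  mag <- dft_magnitude(x)
  half <- floor(n / 2)
  freqs <- (1:half) / n                       # one-sided, DC excluded
  grid <- seq_len(n_bins) / (2 * n_bins)      # (0, 0.5]
  v <- stats::approx(x = freqs, y = mag[2:(half + 1L)], xout = grid,
                     rule = 2)$y
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(numeric(n_bins))
  v / nrm
}

#' Build the trial-by-feature matrix
#'
#' One row per trial. Depending on `cfg$feature_kind`:
#' * `position_freq`: concatenated [frequency_features()] of every feature
#'   channel and axis of the filtered positions (trunk-only camera markers
#'   are excluded; they feed labeling, not clustering).
#' * `accel_freq`: per channel, the acceleration is derived, collapsed to a
#'   1D magnitude, and summarized spectrally; the trial-mean of each
#'   magnitude series is appended as one extra scalar column per channel.
#' * `merged`: column concatenation of both.
#'
#' @param records List of [subject_record()] objects (homogeneous device).
#' @param cfg A [pipeline_config()].
#' @return A `feature_matrix` object: nonnegative matrix `X`, `feature_kind`,
#'   `instance_index` data frame (subject_id, task, repetition) and
#'   `feature_names`.
#' @export
build_feature_matrix <- function(records, cfg) {
  trials <- cohort_trials(records)
  if (!length(trials)) stop("no trials in cohort", call. = FALSE)
  devs <- unique(vapply(trials, `[[`, character(1), "device"))
  if (length(devs) != 1L)
    stop("mixed device profiles in cohort: ", paste(devs, collapse = ", "),
         call. = FALSE)
  if (devs != cfg$device_profile)
    stop(sprintf("cohort device '%s' does not match config profile '%s'",
                 devs, cfg$device_profile), call. = FALSE)
  prof <- device_profile(devs)
  nb <- cfg$n_freq_bins

  rows <- lapply(trials, function(tr) {
    f <- butterworth_lowpass(tr, cfg$cutoff_hz)
    pos <- acc <- numeric(0)
    pos_names <- acc_names <- character(0)
    if (cfg$feature_kind %in% c("position_freq", "merged")) {
      for (ch in prof$feature_channels) for (ax in 1:3) {
        pos <- c(pos, frequency_features(f$channels[[ch]][, ax], nb))
        pos_names <- c(pos_names,
                       sprintf("pos_%s_%s_b%02d", ch, c("x", "y", "z")[ax],
                               seq_len(nb)))
      }
    }
    if (cfg$feature_kind %in% c("accel_freq", "merged")) {
      a3d <- derive_acceleration(f)
      for (ch in prof$feature_channels) {
        mag <- magnitude_1d(a3d[[ch]], f$sampling_rate)
        acc <- c(acc, frequency_features(mag$values, nb), mean(mag$values))
        acc_names <- c(acc_names,
                       sprintf("acc_%s_b%02d", ch, seq_len(nb)),
                       sprintf("acc_%s_mean", ch))
      }
    }
    list(v = c(pos, acc), names = c(pos_names, acc_names))
  })
  X <- do.call(rbind, lapply(rows, `[[`, "v"))
  colnames(X) <- rows[[1L]]$names
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  structure(list(
    X = X,
    feature_kind = cfg$feature_kind,
    instance_index = data.frame(
      subject_id = vapply(trials, `[[`, character(1), "subject_id"),
      task = vapply(trials, `[[`, character(1), "task"),
      repetition = vapply(trials, `[[`, integer(1), "repetition")),
    feature_names = colnames(X)), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d instances x %d features (%s)\n",
              nrow(x$X), ncol(x$X), x$feature_kind))
  invisible(x)
}
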