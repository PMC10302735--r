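# Data model: motion trials, subject records, device profiles.

#' Device profiles
#'
#' A device profile fixes the sampling rate, the named body channels carrying
#' 3D position series, and the subset of channels used for trunk-displacement
#' labeling. The `wearable` profile models a 5-segment IMU suit recording at
#' 60 Hz (hand, shoulder, upper arm, forearm and the sternum sensor `"T8"`,
#' 15 position channels in total); the `camera` profile models a marker-based
#' optical capture at 200 Hz with 9 upper-limb feature markers (27 channels)
#' plus 4 trunk markers that feed labeling only, never the feature matrix.
#'
#' @param device `"wearable"` or `"camera"`.
#' @return A list with elements `device`, `sampling_rate`, `channels`,
#'   `feature_channels` and `trunk_channels`.
#' @examples
#' device_profile("wearable")$sampling_rate  # 60
#' length(device_profile("camera")$feature_channels)  # 9
#' @export
device_profile <- function(device = c("wearable", "camera")) {
  device <- match.arg(device)
  if (device == "wearable") {
    feat <- c("hand", "shoulder", "upper_arm", "forearm", "T8")
    list(device = device, sampling_rate = 60,
         channels = feat, feature_channels = feat, trunk_channels = "T8")
  } else {
    feat <- c("wrist_radial", "wrist_ulnar", "forearm", "humerus_lateral",
              "humerus_medial", "elbow_lateral", "elbow_medial",
              "acromion", "scapula")
    trunk <- c("sternum_upper", "sternum_lower", "spine_c7", "spine_t8")
    list(device = device, sampling_rate = 200,
         channels = c(feat, trunk), feature_channels = feat,
         trunk_channels = trunk)
  }
}

#' The four grasping tasks
#' @return Character vector of task names.
#' @export
grasping_tasks <- function() c("glass", "phone", "cup", "apple")

#' Construct a motion trial
#'
#' One recording of a subject performing one repetition of one grasping task:
#' an ordered set of named channels, each a `T x 3` matrix of x/y/z positions
#' in millimetres sampled at a fixed rate.
#'
#' @param subject_id Subject identifier.
#' @param device `"wearable"` or `"camera"`.
#' @param task One of [grasping_tasks()].
#' @param repetition Integer 1-3.
#' @param sampling_rate Hz; defaults to the device profile rate.
#' @param channels Named list of `T x 3` numeric matrices (columns x, y, z),
#'   all of identical length `T >= 20`.
#' @param trunk_channels Channel names used for trunk displacement; defaults
#'   to the device profile.
#' @return A validated `motion_trial` object.
#' @export
motion_trial <- function(subject_id, device, task, repetition,
                         channels, sampling_rate = NULL,
                         trunk_channels = NULL) {
  prof <- device_profile(device)
  if (is.null(sampling_rate)) sampling_rate <- prof$sampling_rate
  if (is.null(trunk_channels)) trunk_channels <- prof$trunk_channels
  tr <- structure(
    list(subject_id = as.character(subject_id), device = prof$device,
         task = task, repetition = as.integer(repetition),
         sampling_rate = sampling_rate,
         channels = channels, trunk_channels = trunk_channels),
    class = "motion_trial")
  validate_motion_trial(tr)
  tr
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("<motion_trial> %s / %s rep %d (%s, %g Hz)\n",
              x$subject_id, x$task, x$repetition, x$device, x$sampling_rate))
  cat(sprintf("  %d channels x %d samples; trunk: %s\n",
              length(x$channels), n_samples(x),
              paste(x$trunk_channels, collapse = ", ")))
  invisible(x)
}

n_samples <- function(trial) nrow(trial$channels[[1L]])

validate_motion_trial <- function(tr) {
  if (!tr$task %in% grasping_tasks())
    stop("unknown task '", tr$task, "'; expected one of ",
         paste(grasping_tasks(), collapse = ", "), call. = FALSE)
  if (!(tr$repetition %in% 1:3))
    stop("repetition must be 1, 2 or 3", call. = FALSE)
  if (!is.numeric(tr$sampling_rate) || tr$sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)
  prof <- device_profile(tr$device)
  if (tr$sampling_rate != prof$sampling_rate)
    stop(sprintf("device '%s' requires sampling_rate %g Hz, got %g",
                 tr$device, prof$sampling_rate, tr$sampling_rate),
         call. = FALSE)
  if (length(tr$channels) == 0L || is.null(names(tr$channels)))
    stop("channels must be a non-empty named list", call. = FALSE)
  lens <- vapply(tr$channels, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must share the same length; got lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  if (lens[1L] < 20L)
    stop("channel series must have at least 20 samples, got ", lens[1L],
         call. = FALSE)
  bad <- vapply(tr$channels, function(m) ncol(m) != 3L || !is.numeric(m) ||
                  anyNA(m) || any(!is.finite(m)), logical(1))
  if (any(bad))
    stop("channels must be finite numeric T x 3 matrices; offending: ",
         paste(names(tr$channels)[bad], collapse = ", "), call. = FALSE)
  if (length(tr$trunk_channels) == 0L)
    stop("trunk_channels must be non-empty", call. = FALSE)
  missing_trunk <- setdiff(tr$trunk_channels, names(tr$channels))
  if (length(missing_trunk))
    stop("trunk channel(s) missing from trial: ",
         paste(missing_trunk, collapse = ", "), call. = FALSE)
  missing_prof <- setdiff(prof$channels, names(tr$channels))
  if (length(missing_prof))
    stop(sprintf("trial lacks channel(s) required by the '%s' profile: %s",
                 tr$device, paste(missing_prof, collapse = ", ")),
         call. = FALSE)
  invisible(tr)
}

#' Construct a subject record
#'
#' Couples a subject's trials with their Fugl-Meyer upper-extremity score
#' (FMA-UE, 0-66; lower = more impaired) and affected side.
#'
#' @param subject_id Subject identifier.
#' @param fma_ue Integer FMA-UE score in 0-66.
#' @param affected_side `"left"` or `"right"`.
#' @param trials List of [motion_trial()] objects for this subject.
#' @return A validated `subject_record` object.
#' @export
subject_record <- function(subject_id, fma_ue, affected_side, trials) {
  affected_side <- match.arg(affected_side, c("left", "right"))
  rec <- structure(
    list(subject_id = as.character(subject_id), fma_ue = as.integer(fma_ue),
         affected_side = affected_side, trials = trials),
    class = "subject_record")
  validate_subject_record(rec)
  rec
}

validate_subject_record <- function(rec) {
  if (is.na(rec$fma_ue) || rec$fma_ue < 0L || rec$fma_ue > 66L)
    stop("fma_ue must be an integer in 0-66, got ", rec$fma_ue, call. = FALSE)
  for (tr in rec$trials) {
    validate_motion_trial(tr)
    if (tr$subject_id != rec$subject_id)
      stop(sprintf("trial subject_id '%s' does not match record '%s'",
                   tr$subject_id, rec$subject_id), call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s  FMA-UE %d (%s side), %d trials\n",
              x$subject_id, x$fma_ue, x$affected_side, length(x$trials)))
  invisible(x)
}

# flat list of every trial in a cohort, in subject/task/repetition order
cohort_trials <- function(records) {
  unlist(lapply(records, function(r) r$trials), recursive = FALSE)
}
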