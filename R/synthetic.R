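# Synthetic cohort generator: minimum-jerk reach-hold-return trials with
# class-dependent movement smoothness and trunk compensation, plus toy
# partition ensembles for solver tests.

#' Specification of a synthetic cohort
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' 4 grasping tasks x 3 repetitions per subject; smooth minimum-jerk limb
#' reaches whose smoothness degrades with severity (corrective
#' sub-movements and 4.5 Hz tremor, as impaired reaching is slower and more
#' segmented); a forward trunk-lean bump whose amplitude grows with
#' severity (compensatory trunk recruitment); additive Gaussian sensor
#' noise; and FMA-UE scores sampled inside the band matching each subject's
#' class so ground truth is self-consistent.
#'
#' @param n_subjects Number of subjects.
#' @param class_mix Named probabilities over severity classes
#'   (`non-severe`, `mild`, `severe`); default an even severe / non-severe
#'   split.
#' @param device `"wearable"` or `"camera"`.
#' @param duration_s Trial duration in seconds (default 4: 0.5 s rest,
#'   reach, hold, return).
#' @param trunk_amp_mm Named mean trunk-lean amplitudes per class (mm),
#'   strictly increasing with severity; defaults 5 / 20 / 40.
#' @param tremor_amp_mm Named tremor amplitudes per class (mm); defaults
#'   0.2 / 1.5 / 3.
#' @param n_submovements Named corrective sub-movement counts per class;
#'   defaults 0 / 2 / 4.
#' @param noise_sd_mm Sensor noise standard deviation (mm, default 1).
#' @param seed Master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 20L,
                        class_mix = c("non-severe" = 0.5, "severe" = 0.5),
                        device = "wearable",
                        duration_s = 4,
                        trunk_amp_mm = c("non-severe" = 5, "mild" = 20,
                                         "severe" = 40),
                        tremor_amp_mm = c("non-severe" = 0.2, "mild" = 1.5,
                                          "severe" = 3),
                        n_submovements = c("non-severe" = 0L, "mild" = 2L,
                                           "severe" = 4L),
                        noise_sd_mm = 1,
                        seed = 1L) {
  cls <- names(class_mix)
  if (!all(cls %in% c("non-severe", "mild", "severe")))
    stop("class_mix names must be non-severe / mild / severe", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1", call. = FALSE)
  amps <- trunk_amp_mm[c("non-severe", "mild", "severe")]
  if (any(diff(amps[!is.na(amps)]) <= 0))
    stop("trunk amplitudes must increase with severity", call. = FALSE)
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), class_mix = class_mix,
                 device = device, duration_s = duration_s,
                 trunk_amp_mm = trunk_amp_mm, tremor_amp_mm = tremor_amp_mm,
                 n_submovements = n_submovements,
                 noise_sd_mm = noise_sd_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

# minimum-jerk position profile s(tau) on [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# FMA bands per class (consistent with fma_to_severity defaults)
fma_band <- function(cls) switch(cls,
  "severe" = c(0L, 28L), "mild" = c(29L, 42L), "non-severe" = c(43L, 66L))

#' Generate a synthetic cohort
#'
#' Deterministic given the spec's seed. Per subject: a severity class is
#' drawn from the mix and an FMA-UE score sampled uniformly in that class's
#' band; per trial, limb channels follow a minimum-jerk reach-hold-return
#' with class-dependent tremor and corrective sub-movements, the trunk
#' channel(s) follow a forward-lean bump with peak amplitude
#' Normal(class mean, 0.1 x mean) truncated at zero, and Gaussian noise is
#' added everywhere. The first 0.5 s are quiet rest so the 10-sample
#' trunk baseline is clean.
#'
#' @param spec A [cohort_spec()].
#' @return List of [subject_record()] objects.
#' @export
generate_cohort <- function(spec) {
  prof <- device_profile(spec$device)
  fs <- prof$sampling_rate
  nt <- round(spec$duration_s * fs)
  t <- (seq_len(nt) - 1L) / fs
  set.seed(spec$seed)
  classes <- sample(names(spec$class_mix), spec$n_subjects, replace = TRUE,
                    prob = spec$class_mix)
  # per-channel reach extents (mm): distal segments travel farther
  extent <- if (spec$device == "wearable")
    c(hand = 320, shoulder = 40, upper_arm = 120, forearm = 220, T8 = 0)
  else c(wrist_radial = 300, wrist_ulnar = 295, forearm = 210,
         humerus_lateral = 120, humerus_medial = 115, elbow_lateral = 160,
         elbow_medial = 155, acromion = 45, scapula = 35)

  lapply(seq_len(spec$n_subjects), function(si) {
    cls <- classes[si]
    sid <- sprintf("S%03d", si)
    fma <- sample(seq(fma_band(cls)[1], fma_band(cls)[2]), 1L)
    trials <- list()
    for (task in grasping_tasks()) for (rep in 1:3) {
      trials[[length(trials) + 1L]] <-
        simulate_trial(sid, spec, prof, cls, task, rep, t, extent)
    }
    subject_record(sid, fma, affected_side = if (si %% 2L) "right" else "left",
                   trials = trials)
  })
}

simulate_trial <- function(sid, spec, prof, cls, task, rep, t, extent) {
  fs <- prof$sampling_rate
  nt <- length(t)
  rest <- 0.5
  dur <- max(t) + 1 / fs
  reach_t <- (dur - rest) * 0.3
  hold_t <- (dur - rest) * 0.3
  # phase profile: 0 at rest, up during reach, 1 in hold, back in return
  phase <- ifelse(t < rest, 0,
           ifelse(t < rest + reach_t, min_jerk((t - rest) / reach_t),
           ifelse(t < rest + reach_t + hold_t, 1,
                  1 - min_jerk((t - rest - reach_t - hold_t) /
                               (dur - rest - reach_t - hold_t)))))
  tremor_a <- spec$tremor_amp_mm[[cls]]
  nsub <- spec$n_submovements[[cls]]
  moving <- phase > 0 & phase < 1

  channels <- list()
  for (ch in prof$channels) {
    is_trunk <- ch %in% prof$trunk_channels
    amp <- if (is_trunk) {
      mu <- spec$trunk_amp_mm[[cls]]
      max(stats::rnorm(1L, mu, 0.1 * mu), 0)
    } else extent[[ch]]
    base <- stats::runif(3L, -50, 50)           # resting position offset
    # direction of travel, mostly forward (x)
    dirv <- c(1, stats::runif(1L, -0.3, 0.3), stats::runif(1L, -0.2, 0.4))
    dirv <- dirv / sqrt(sum(dirv^2))
    shape <- if (is_trunk) sin(pmin(pmax(phase, 0), 1) * pi / 2)^2 else phase
    m <- outer(shape * amp, dirv)
    if (!is_trunk && nsub > 0L) {
      # corrective sub-movements: short minimum-jerk out-and-back bumps
      for (s in seq_len(nsub)) {
        t0 <- stats::runif(1L, rest, max(rest + 0.05, dur - 0.5))
        w <- stats::runif(1L, 0.25, 0.45)
        bump <- min_jerk((t - t0) / (w / 2)) * (t >= t0 & t < t0 + w / 2) +
          (1 - min_jerk((t - t0 - w / 2) / (w / 2))) *
          (t >= t0 + w / 2 & t < t0 + w)
        m <- m + outer(bump * stats::runif(1L, 8, 18), dirv)
      }
    }
    if (!is_trunk && tremor_a > 0) {
      ph <- stats::runif(3L, 0, 2 * pi)
      trem <- vapply(1:3, function(a)
        tremor_a * sin(2 * pi * 4.5 * t + ph[a]) * moving, numeric(nt))
      m <- m + trem
    }
    m <- sweep(m, 2L, base, `+`)
    m <- m + matrix(stats::rnorm(nt * 3L, 0, spec$noise_sd_mm), nt, 3L)
    colnames(m) <- c("x", "y", "z")
    channels[[ch]] <- m
  }
  motion_trial(sid, spec$device, task, rep, channels)
}

#' Generate a toy partition ensemble with a planted consensus
#'
#' A planted partition over `n` instances is copied `T` times; each member
#' re-labels each instance uniformly at random with probability
#' `1 - agreement`.
#'
#' @param n Number of instances.
#' @param k Number of clusters.
#' @param agreement Probability in `[0, 1]` of keeping the planted label.
#' @param T Number of members.
#' @param seed Seed.
#' @return A [partition_ensemble()] with attribute `"truth"` (the planted
#'   0-based labels).
#' @export
generate_toy_ensemble <- function(n, k, agreement = 0.8, T = 5L, seed = 1L) {
  if (n < k) stop("n must be >= k", call. = FALSE)
  set.seed(seed)
  truth <- c(seq_len(k) - 1L,
             sample(0:(k - 1L), n - k, replace = TRUE))[sample(n)]
  parts <- lapply(seq_len(T), function(tt) {
    lab <- truth
    flip <- stats::runif(n) > agreement
    lab[flip] <- sample(0:(k - 1L), sum(flip), replace = TRUE)
    partition(lab, k, method = sprintf("member%02d", tt), seed = seed)
  })
  ens <- partition_ensemble(parts)
  attr(ens, "truth") <- truth
  ens
}
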