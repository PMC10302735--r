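# Trunk displacement, trunk-based cluster labeling, FMA ground truth,
# evaluation metrics.

severity_classes <- function(k)
  if (k == 2L) c("non-severe", "severe") else c("non-severe", "mild", "severe")

#' Trunk displacement of a trial
#'
#' For each trunk channel the per-axis mean of the first 10 samples is
#' subtracted (the resting baseline), and the per-step displacement is the
#' sum of the per-axis magnitudes |TD_x| + |TD_y| + |TD_z| (absolute values,
#' so oscillatory sway cannot cancel; set `signed_sum = TRUE` for the
#' literal signed sum). Camera trials average the four trunk markers'
#' series.
#'
#' @param trial A (typically filtered) [motion_trial()].
#' @param signed_sum Use the signed per-axis sum instead of absolute values.
#' @return A `trunk_displacement` list: per-step `series` (mm),
#'   `trial_mean`, and per-axis means `components`.
#' @export
trunk_displacement <- function(trial, signed_sum = FALSE) {
  if (n_samples(trial) < 10L)
    stop("trunk displacement needs >= 10 samples for the baseline",
         call. = FALSE)
  missing <- setdiff(trial$trunk_channels, names(trial$channels))
  if (length(missing))
    stop("missing trunk channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  per_chan <- lapply(trial$trunk_channels, function(ch) {
    m <- trial$channels[[ch]]
    base <- colMeans(m[1:10, , drop = FALSE])
    d <- sweep(m, 2L, base)
    if (!signed_sum) d <- abs(d)
    list(series = rowSums(d), comp = colMeans(d))
  })
  series <- rowMeans(vapply(per_chan, `[[`, numeric(n_samples(trial)),
                            "series"))
  comp <- rowMeans(vapply(per_chan, `[[`, numeric(3L), "comp"))
  structure(list(series = series, trial_mean = mean(series),
                 components = setNames(comp, c("x", "y", "z"))),
            class = "trunk_displacement")
}

#' Per-trial mean trunk displacement across a cohort
#'
#' Applies the configured low-pass filter to every trial and returns each
#' trial's mean trunk displacement, aligned with the instance order of
#' [build_feature_matrix()].
#'
#' @param records List of [subject_record()] objects.
#' @param cfg A [pipeline_config()].
#' @return Numeric vector (mm), one value per trial.
#' @export
cohort_trunk_means <- function(records, cfg) {
  vapply(cohort_trials(records), function(tr)
    trunk_displacement(butterworth_lowpass(tr, cfg$cutoff_hz),
                       signed_sum = cfg$signed_sum)$trial_mean,
    numeric(1))
}

#' Label consensus clusters by trunk displacement
#'
#' Ranks clusters by their mean per-instance trunk displacement: the lowest
#' mean is the least severe class, the highest is severe (more compensatory
#' trunk motion = more severe). Ties rank the lower cluster id as less
#' severe.
#'
#' @param p A [partition()].
#' @param td Per-instance mean trunk displacements (mm), aligned with
#'   `p$labels`.
#' @param k Number of clusters / severity classes.
#' @return A `severity_labeling`: `cluster_class` (cluster id -> class),
#'   `cluster_means`, and the per-instance `classes` factor.
#' @export
label_clusters <- function(p, td, k = p$k) {
  if (length(td) != length(p$labels))
    stop("td not aligned with partition", call. = FALSE)
  sizes <- tabulate(p$labels + 1L, k)
  if (any(sizes == 0L)) stop("empty cluster cannot be labelled",
                             call. = FALSE)
  means <- vapply(0:(k - 1L), function(c) mean(td[p$labels == c]),
                  numeric(1))
  ord <- order(means, 0:(k - 1L))      # ties -> lower id less severe
  classes <- severity_classes(k)
  cluster_class <- character(k)
  cluster_class[ord] <- classes
  structure(list(
    cluster_class = setNames(cluster_class, 0:(k - 1L)),
    cluster_means = setNames(means, 0:(k - 1L)),
    classes = factor(cluster_class[p$labels + 1L], levels = classes)),
    class = "severity_labeling")
}

#' Map an FMA-UE score to a severity class
#'
#' Half-open banding: for `k = 2`, scores strictly below the threshold
#' (default 29) are severe; for `k = 3` the default bands are
#' severe `[0, 29)`, mild `[29, 43)`, non-severe `[43, 66]`.
#'
#' @param fma_ue Integer score(s) in 0-66.
#' @param k 2 or 3.
#' @param thresholds `list(k2 = 29, k3 = c(29, 43))`-style overrides.
#' @return Factor of severity classes, least to most severe levels.
#' @export
fma_to_severity <- function(fma_ue, k = 2L,
                            thresholds = list(k2 = 29L, k3 = c(29L, 43L))) {
  if (any(fma_ue < 0 | fma_ue > 66))
    stop("fma_ue out of range 0-66", call. = FALSE)
  classes <- severity_classes(k)
  cls <- if (k == 2L) {
    ifelse(fma_ue < thresholds$k2, "severe", "non-severe")
  } else {
    ifelse(fma_ue < thresholds$k3[1], "severe",
           ifelse(fma_ue < thresholds$k3[2], "mild", "non-severe"))
  }
  factor(cls, levels = classes)
}

#' Evaluate predicted severity against ground truth
#'
#' Confusion matrix over severity classes with class-support-weighted
#' precision, recall and F1 plus overall accuracy. Weighted recall equals
#' accuracy by the algebra of support weighting. Classes never predicted
#' contribute precision 0 (zero-division convention).
#'
#' @param pred,truth Factors (or vectors) of severity classes, aligned.
#' @return A `metrics_report`: `accuracy`, `precision`, `recall`, `f_score`,
#'   `confusion`.
#' @export
evaluate_severity <- function(pred, truth) {
  lev <- union(levels(factor(truth)), levels(factor(pred)))
  pred <- factor(pred, levels = lev)
  truth <- factor(truth, levels = lev)
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  conf <- table(truth = truth, pred = pred)
  support <- rowSums(conf)
  w <- support / sum(support)
  prec_c <- diag(conf) / colSums(conf)
  prec_c[!is.finite(prec_c)] <- 0
  rec_c <- diag(conf) / support
  rec_c[!is.finite(rec_c)] <- 0
  f_c <- ifelse(prec_c + rec_c > 0,
                2 * prec_c * rec_c / (prec_c + rec_c), 0)
  structure(list(accuracy = sum(diag(conf)) / sum(conf),
                 precision = sum(w * prec_c),
                 recall = sum(w * rec_c),
                 f_score = sum(w * f_c),
                 confusion = conf), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.3f  precision %.3f  recall %.3f  F %.3f\n",
    x$accuracy, x$precision, x$recall, x$f_score))
  print(x$confusion)
  invisible(x)
}
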