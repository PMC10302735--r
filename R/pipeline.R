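# End-to-end glue: cohort -> features -> ensemble -> consensus -> trunk
# labeling -> metrics.

#' Run the full severity-assessment pipeline
#'
#' Filters and featurizes the cohort, builds the baseline ensemble, runs
#' the configured consensus solver, labels the consensus clusters by mean
#' trunk displacement, maps each subject's FMA-UE score to a ground-truth
#' class (trials inherit their subject's class), and evaluates.
#'
#' @param records List of [subject_record()] objects.
#' @param cfg A [pipeline_config()].
#' @return A `severity_result`: `partition`, `labeling`, `metrics`,
#'   `truth`, `pred`, `trunk_means`, `features`, `ensemble`.
#' @export
run_pipeline <- function(records, cfg = pipeline_config()) {
  fm <- build_feature_matrix(records, cfg)
  k <- cfg$k_clusters
  seed <- cfg$random_seed
  ens <- build_ensemble(fm, cfg$methods, k, seed)
  p <- if (cfg$solver == "psa_mnmf")
    mnmf_consensus(average_consensus(ens), k,
                   seed = derive_seed(seed, 1000L))
  else consensus_partition(ens, k, cfg$solver, seed = derive_seed(seed, 1000L))
  td <- cohort_trunk_means(records, cfg)
  labeling <- label_clusters(p, td, k)
  fma_by_subject <- setNames(vapply(records, `[[`, integer(1), "fma_ue"),
                             vapply(records, `[[`, character(1),
                                    "subject_id"))
  truth <- fma_to_severity(fma_by_subject[fm$instance_index$subject_id],
                           k, cfg$fma_thresholds)
  metrics <- evaluate_severity(labeling$classes, truth)
  structure(list(partition = p, labeling = labeling, metrics = metrics,
                 truth = truth, pred = labeling$classes,
                 trunk_means = td, features = fm, ensemble = ens,
                 config = cfg), class = "severity_result")
}

#' @export
print.severity_result <- function(x, ...) {
  cat(sprintf("<severity_result> %d trials, k=%d, solver=%s\n",
              length(x$partition$labels), x$partition$k, x$config$solver))
  print(x$metrics)
  invisible(x)
}
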