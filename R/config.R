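# Pipeline configuration: defaults, validation, YAML round trip.

#' Pipeline configuration
#'
#' Central knobs for the severity-assessment pipeline. Defaults follow the
#' study settings: second-order low-pass Butterworth at 10 Hz (wearable) or
#' 20 Hz (camera), frequency-domain features, 2- or 3-cluster consensus, and
#' a 100-run exhaustive combination search reporting the top 10 subsets.
#'
#' @param device_profile `"wearable"` or `"camera"`.
#' @param cutoff_hz Low-pass filter cutoff in Hz. `NULL` picks the profile
#'   default (10 wearable / 20 camera). Must be below Nyquist.
#' @param feature_kind `"position_freq"`, `"accel_freq"` or `"merged"`.
#' @param n_freq_bins Spectral bins retained per channel/axis (default 16).
#' @param k_clusters 2 (severe / non-severe) or 3 (adds mild).
#' @param solver Consensus solver: `"psa_mnmf"`, `"mcla"`, `"cspa"`,
#'   `"hbgf"` or `"hgpa"`.
#' @param methods Baseline clustering methods forming the ensemble.
#' @param n_runs Exhaustive-search repetitions (default 100).
#' @param top_m Best combinations kept per run (default 10).
#' @param random_seed Master seed for every stochastic stage.
#' @param fma_thresholds List with elements `k2` (scalar: scores strictly
#'   below are severe) and `k3` (two cut points splitting 0-66 into
#'   severe / mild / non-severe bands).
#' @param signed_sum Use the literal signed per-axis sum for trunk
#'   displacement instead of the absolute-value convention (default FALSE).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(device_profile = "wearable",
                            cutoff_hz = NULL,
                            feature_kind = c("merged", "position_freq", "accel_freq"),
                            n_freq_bins = 16L,
                            k_clusters = 2L,
                            solver = c("psa_mnmf", "mcla", "cspa", "hbgf", "hgpa"),
                            methods = baseline_methods(),
                            n_runs = 100L,
                            top_m = 10L,
                            random_seed = 1L,
                            fma_thresholds = list(k2 = 29L, k3 = c(29L, 43L)),
                            signed_sum = FALSE) {
  prof <- device_profile(device_profile)
  if (is.null(cutoff_hz))
    cutoff_hz <- if (prof$device == "wearable") 10 else 20
  cfg <- structure(list(
    device_profile = prof$device,
    cutoff_hz = cutoff_hz,
    feature_kind = match.arg(feature_kind),
    n_freq_bins = as.integer(n_freq_bins),
    k_clusters = as.integer(k_clusters),
    solver = match.arg(solver),
    methods = methods,
    n_runs = as.integer(n_runs),
    top_m = as.integer(top_m),
    random_seed = as.integer(random_seed),
    fma_thresholds = fma_thresholds,
    signed_sum = isTRUE(signed_sum)), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  prof <- device_profile(cfg$device_profile)
  if (cfg$cutoff_hz <= 0 || cfg$cutoff_hz >= prof$sampling_rate / 2)
    stop(sprintf("cutoff_hz must lie in (0, %g) for the %s profile",
                 prof$sampling_rate / 2, prof$device), call. = FALSE)
  if (!cfg$k_clusters %in% c(2L, 3L))
    stop("k_clusters must be 2 or 3", call. = FALSE)
  if (cfg$n_freq_bins < 2L) stop("n_freq_bins must be >= 2", call. = FALSE)
  if (cfg$n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  if (cfg$top_m < 1L) stop("top_m must be >= 1", call. = FALSE)
  bad <- setdiff(cfg$methods, baseline_methods())
  if (length(bad))
    stop("unknown baseline method(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  th <- cfg$fma_thresholds
  if (length(th$k3) != 2L || th$k3[1] >= th$k3[2])
    stop("fma_thresholds$k3 must be two increasing cut points", call. = FALSE)
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#' @param path File path.
#' @param cfg A [pipeline_config()] object.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$fma_thresholds <- if (is.null(raw$fma_thresholds)) NULL else
    list(k2 = as.integer(raw$fma_thresholds$k2),
         k3 = as.integer(unlist(raw$fma_thresholds$k3)))
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
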