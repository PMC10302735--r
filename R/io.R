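# On-disk cohort schema: one long-format CSV per trial
# (t_index, channel, axis, value_mm), a cohort-level subjects.csv
# (subject_id, fma_ue, affected_side), and a JSON manifest.

trial_file_name <- function(tr)
  sprintf("%s_%s_rep%d.csv", tr$subject_id, tr$task, tr$repetition)

#' Write a cohort to disk
#'
#' Serializes each trial as a long-format CSV with columns `t_index`
#' (0-based sample index), `channel`, `axis` (x/y/z) and `value_mm`, plus a
#' `subjects.csv` metadata table, and returns a JSON manifest with per-file
#' row counts and MD5 checksums.
#'
#' @param records List of [subject_record()] objects.
#' @param path Output directory (created if absent).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_cohort <- function(records, path) {
  for (rec in records) validate_subject_record(rec)
  trials <- cohort_trials(records)
  keys <- vapply(trials, trial_file_name, character(1))
  if (anyDuplicated(keys))
    stop("duplicate (subject, task, repetition) key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)

  files <- character(0)
  for (tr in trials) {
    long <- do.call(rbind, lapply(names(tr$channels), function(ch) {
      m <- tr$channels[[ch]]
      data.frame(t_index = rep(0:(nrow(m) - 1L), 3L),
                 channel = ch,
                 axis = rep(c("x", "y", "z"), each = nrow(m)),
                 # %.17g guarantees the double survives the text round trip
                 value_mm = sprintf("%.17g", as.vector(m)))
    }))
    f <- file.path(path, trial_file_name(tr))
    write.csv(long, f, row.names = FALSE)
    files <- c(files, f)
  }
  subjects <- data.frame(
    subject_id = vapply(records, `[[`, character(1), "subject_id"),
    fma_ue = vapply(records, `[[`, integer(1), "fma_ue"),
    affected_side = vapply(records, `[[`, character(1), "affected_side"))
  write.csv(subjects, file.path(path, "subjects.csv"), row.names = FALSE)

  manifest <- list(
    n_subjects = length(records),
    n_trials = length(trials),
    device = if (length(trials)) trials[[1L]]$device else NA_character_,
    files = lapply(seq_along(files), function(i) list(
      file = basename(files[i]),
      n_samples = n_samples(trials[[i]]),
      md5 = unname(tools::md5sum(files[i])))))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort from disk
#'
#' Reads the schema written by [write_cohort()] and validates every trial
#' against the declared device profile (channel set, sampling-rate pairing,
#' trunk channels present, equal series lengths, FMA-UE in 0-66).
#'
#' @param path Directory containing trial CSVs and `subjects.csv`.
#' @param profile `"wearable"` or `"camera"`.
#' @return List of validated [subject_record()] objects.
#' @export
read_cohort <- function(path, profile = c("wearable", "camera")) {
  profile <- match.arg(profile)
  subj_path <- file.path(path, "subjects.csv")
  if (!file.exists(subj_path))
    stop("subjects.csv not found under ", path, call. = FALSE)
  subjects <- read.csv(subj_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "fma_ue", "affected_side")
  if (!all(needed %in% names(subjects)))
    stop("subjects.csv must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)

  trial_files <- setdiff(list.files(path, pattern = "\\.csv$"), "subjects.csv")
  parsed <- regmatches(trial_files,
                       regexec("^(.+)_([a-z]+)_rep([0-9]+)\\.csv$", trial_files))
  lapply(seq_len(nrow(subjects)), function(i) {
    sid <- as.character(subjects$subject_id[i])
    mine <- which(vapply(parsed, function(p)
      length(p) == 4L && p[2] == sid, logical(1)))
    trials <- lapply(mine, function(j) {
      p <- parsed[[j]]
      long <- read.csv(file.path(path, trial_files[j]),
                       stringsAsFactors = FALSE)
      chans <- split(long, long$channel)
      channels <- lapply(chans, function(d) {
        d <- d[order(match(d$axis, c("x", "y", "z")), d$t_index), ]
        n <- nrow(d) / 3L
        if (n != floor(n))
          stop("trial file ", trial_files[j],
               " has unbalanced axis rows for channel ", d$channel[1L],
               call. = FALSE)
        matrix(d$value_mm, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
      })
      motion_trial(subject_id = sid, device = profile, task = p[3],
                   repetition = as.integer(p[4]), channels = channels)
    })
    subject_record(sid, subjects$fma_ue[i], subjects$affected_side[i], trials)
  })
}
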