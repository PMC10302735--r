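# Exhaustive search over baseline-method combinations.

#' Exhaustive search for the best method combination
#'
#' Enumerates every subset of at least two baseline methods (247 subsets for
#' 8 methods). Each run re-randomizes both the baseline clusterings and the
#' factorization with a fresh derived seed, scores every subset's PSA-MNMF
#' consensus with the supplied evaluation callback (an F-score in the
#' pipeline), and keeps the `top_m` best. After `n_runs` runs the subset
#' appearing most often across the top lists is selected; ties break toward
#' the higher mean score, then the smaller subset, then lexicographic order.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param methods Candidate baseline methods.
#' @param k Number of clusters.
#' @param score_fn Callback `function(partition) -> numeric` (higher =
#'   better), e.g. the trunk-labeling F-score against FMA-derived truth.
#' @param n_runs Number of repetitions (default 100).
#' @param top_m Best combinations kept per run (default 10).
#' @param seed Master seed.
#' @param restarts MNMF restarts per consensus (default 5).
#' @param fit_fn Partitioner passed through to [build_ensemble()].
#' @return A `search_report`: `selected` (character vector of methods),
#'   `frequency` (times each subset entered a top list), `mean_score`,
#'   `runs` (per-run data frames of subset, score, rank), `seed`.
#' @export
exhaustive_search <- function(X, methods = baseline_methods(), k = 2L,
                              score_fn, n_runs = 100L, top_m = 10L,
                              seed = 1L, restarts = 5L,
                              fit_fn = fit_partition) {
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  methods <- sort(methods)
  subsets <- unlist(lapply(2:length(methods), function(m)
    utils::combn(methods, m, simplify = FALSE)), recursive = FALSE)
  ids <- vapply(subsets, paste, character(1), collapse = "+")

  runs <- vector("list", n_runs)
  freq <- setNames(numeric(length(ids)), ids)
  score_sum <- setNames(numeric(length(ids)), ids)
  score_cnt <- setNames(numeric(length(ids)), ids)
  for (r in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, r)
    scores <- vapply(seq_along(subsets), function(s) {
      p <- psa_mnmf_consensus(X, subsets[[s]], k,
                              seed = derive_seed(run_seed, s),
                              restarts = restarts, fit_fn = fit_fn)
      score_fn(p)
    }, numeric(1))
    ord <- order(-scores, ids)            # score desc, id asc on ties
    top <- head(ord, top_m)
    freq[top] <- freq[top] + 1
    score_sum <- score_sum + scores
    score_cnt <- score_cnt + 1
    runs[[r]] <- data.frame(subset = ids[top], score = scores[top],
                            rank = seq_along(top))
  }
  mean_score <- score_sum / score_cnt
  sizes <- lengths(subsets)
  ord <- order(-freq, -mean_score, sizes, ids)
  best_id <- ids[ord[1L]]
  structure(list(selected = subsets[[match(best_id, ids)]],
                 selected_id = best_id,
                 frequency = freq, mean_score = mean_score,
                 runs = runs, seed = seed, n_runs = n_runs, top_m = top_m),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat(sprintf("<search_report> %d runs, top-%d lists\n", x$n_runs, x$top_m))
  cat("  selected:", x$selected_id,
      sprintf("(in %d/%d top lists, mean score %.3f)\n",
              x$frequency[x$selected_id], x$n_runs,
              x$mean_score[x$selected_id]))
  invisible(x)
}

#' Serialize a search report to JSON
#' @param report A `search_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_search_report <- function(report, path) {
  jsonlite::write_json(list(
    selected = report$selected,
    frequency = as.list(report$frequency[report$frequency > 0]),
    mean_score = as.list(round(report$mean_score, 6)),
    n_runs = report$n_runs, top_m = report$top_m, seed = report$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
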