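# Partition and ensemble containers.

#' Baseline clustering methods
#' @return Character vector of the eight supported method names.
#' @export
baseline_methods <- function()
  c("fuzzy_cmeans", "kmeans", "som", "gmm", "dbscan",
    "hierarchical", "spectral", "optics")

#' Construct a hard partition
#'
#' @param labels Integer labels, values in `0..k-1`.
#' @param k Number of clusters.
#' @param method Producing method name (free-form for consensus outputs).
#' @param seed Seed used, if any.
#' @return A `partition` object.
#' @export
partition <- function(labels, k, method = "unknown", seed = NA_integer_) {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0L) || any(labels >= k))
    stop("labels must lie in [0, k)", call. = FALSE)
  if (length(unique(labels)) < 1L) stop("empty partition", call. = FALSE)
  structure(list(labels = labels, k = as.integer(k), method = method,
                 seed = seed), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> n=%d k=%d method=%s  sizes: %s\n",
              length(x$labels), x$k, x$method,
              paste(tabulate(x$labels + 1L, x$k), collapse = "/")))
  invisible(x)
}

#' Construct a partition ensemble
#'
#' @param partitions List of [partition()] objects over the same instances.
#' @return A `partition_ensemble` object.
#' @export
partition_ensemble <- function(partitions) {
  ns <- vapply(partitions, function(p) length(p$labels), integer(1))
  if (length(unique(ns)) != 1L)
    stop("ensemble members disagree on n", call. = FALSE)
  structure(list(partitions = partitions, n = ns[1L]),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> T=%d members over n=%d instances (%s)\n",
              length(x$partitions), x$n,
              paste(vapply(x$partitions, `[[`, character(1), "method"),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize / read an ensemble as an n x T integer label table
#' @param ens A [partition_ensemble()].
#' @param path CSV path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble` an
#'   ensemble.
#' @export
write_ensemble <- function(ens, path) {
  m <- vapply(ens$partitions, `[[`, integer(ens$n), "labels")
  colnames(m) <- vapply(ens$partitions, `[[`, character(1), "method")
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  partition_ensemble(lapply(seq_len(ncol(m)), function(j)
    partition(m[, j], k = max(m[, j]) + 1L, method = colnames(m)[j])))
}
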