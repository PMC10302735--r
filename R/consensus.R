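# Co-association machinery shared by every consensus solver.

#' Connectivity matrix of a partition
#'
#' Binary symmetric `n x n` matrix with unit diagonal: entry (i, j) is 1
#' exactly when i and j share a cluster.
#'
#' @param p A [partition()].
#' @return Integer 0/1 matrix.
#' @export
connectivity <- function(p) {
  outer(p$labels, p$labels, `==`) + 0L
}

#' Averaged co-association (consensus) matrix
#'
#' Elementwise mean of the member connectivity matrices, together with the
#' ensemble dispersion: the mean squared deviation of member co-associations
#' from the average. Dispersion zero means every member induces the same
#' co-association structure.
#'
#' @param ens A [partition_ensemble()] with at least 2 members.
#' @return A `consensus_matrix` object with fields `CM` (entries on the grid
#'   j/T), `T` and `dispersion`.
#' @export
average_consensus <- function(ens) {
  if (length(ens$partitions) < 2L)
    stop("need at least 2 ensemble members", call. = FALSE)
  Ms <- lapply(ens$partitions, connectivity)
  Tt <- length(Ms)
  CM <- Reduce(`+`, Ms) / Tt
  disp <- sum(vapply(Ms, function(M) sum((M - CM)^2), numeric(1))) / Tt
  structure(list(CM = CM, T = Tt, dispersion = disp),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("<consensus_matrix> n=%d, T=%d, dispersion=%.4g\n",
              nrow(x$CM), x$T, x$dispersion))
  invisible(x)
}

#' Pair-disagreement distance between two partitions
#'
#' Counts ordered pairs (i, j) on which the two connectivity matrices
#' disagree. Symmetric, zero on identical cluster structures, invariant to
#' label permutation, and a pseudometric on partitions.
#'
#' @param p1,p2 [partition()] objects over the same instances.
#' @return Nonnegative integer.
#' @export
partition_distance <- function(p1, p2) {
  if (length(p1$labels) != length(p2$labels))
    stop("partitions have different n", call. = FALSE)
  sum(abs(connectivity(p1) - connectivity(p2)))
}

as_consensus <- function(x) {
  if (inherits(x, "consensus_matrix")) return(x)
  if (inherits(x, "partition_ensemble")) return(average_consensus(x))
  stop("expected a partition_ensemble or consensus_matrix", call. = FALSE)
}

#' Averaged normalized mutual information
#'
#' Mean over ensemble members of NMI(candidate, member), where NMI uses
#' natural logarithms and the arithmetic-mean normalization
#' 2 I(X;Y) / (H(X) + H(Y)). A side with zero entropy defines NMI = 0.
#'
#' @param candidate A [partition()].
#' @param ens A [partition_ensemble()].
#' @return Value in `[0, 1]`.
#' @export
anmi <- function(candidate, ens) {
  mean(vapply(ens$partitions, function(p) nmi(candidate$labels, p$labels),
              numeric(1)))
}

#' @rdname anmi
#' @param x,y Integer label vectors of equal length.
#' @export
nmi <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n; py <- colSums(tab) / n
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  pj <- tab / n
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / (rowSums(tab) %o% colSums(tab) / n^2)[nz]))
  2 * mi / (hx + hy)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two hard partitions; 1 for identical
#' cluster structures, about 0 for independent ones.
#'
#' @param x,y Integer label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand <- function(x, y) mclust::adjustedRandIndex(x, y)
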