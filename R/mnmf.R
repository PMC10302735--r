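# The modified symmetric NMF consensus solver:
#   min_{N, L >= 0} || CM - N L N^T ||_F^2
# solved by multiplicative updates along
#   N <- N . (CM N L) / (N N^T CM N L)
#   L <- L . (N^T CM N) / (N^T N L N^T N)
# with a damping exponent on the multiplicative factor (start 1/2, halved
# until the step does not increase the objective; the factor is left
# unchanged when no exponent helps). The undamped rules can overshoot, and
# the solver contract requires a non-increasing objective trace, so descent
# is enforced while keeping the same fixed points. Denominators are floored
# at eps = 1e-12.

mnmf_objective <- function(CM, N, L) sum((CM - N %*% L %*% t(N))^2)

#' Solve the symmetric tri-factorization of a consensus matrix
#'
#' Factorizes `CM ~ N L N^T` with elementwise-nonnegative `N` (n x k) and
#' `L` (k x k, not restricted to diagonal) by damped multiplicative
#' updates from a seeded random initialization (`N ~ U(0.1, 1.1)`,
#' `L = I + U(0, 0.01)`).
#'
#' @param cm A `consensus_matrix` from [average_consensus()], or a bare
#'   symmetric nonnegative matrix.
#' @param k Number of clusters (`k <= n`).
#' @param seed Integer seed for the initialization.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative objective-change convergence threshold (default 1e-7).
#' @param eps Denominator floor (default 1e-12).
#' @return A `factor_pair`: `N`, `L`, the non-increasing objective `trace`,
#'   `iterations`, `converged`, and `orthogonality` (`||N~'N~ - I||_F` after
#'   column normalization, a soft-orthogonality diagnostic).
#' @export
mnmf_solve <- function(cm, k, seed = 1L, max_iter = 500L, tol = 1e-7,
                       eps = 1e-12) {
  CM <- if (inherits(cm, "consensus_matrix")) cm$CM else as.matrix(cm)
  n <- nrow(CM)
  if (k > n) stop("k exceeds n", call. = FALSE)
  if (max(abs(CM - t(CM))) > 1e-8)
    stop("consensus matrix must be symmetric", call. = FALSE)
  set.seed(seed)
  N <- matrix(stats::runif(n * k, 0.1, 1.1), n, k)
  L <- diag(k) + matrix(stats::runif(k * k, 0, 0.01), k, k)
  o <- mnmf_objective(CM, N, L)
  trace <- o
  converged <- FALSE
  step <- function(cur, fac, eval2) {
    # damped multiplicative step with exponent backoff; never ascend
    p <- 0.5
    while (p >= 2^-16) {
      cand <- cur * fac^p
      o2 <- eval2(cand)
      if (o2 <= o + 1e-12) return(list(x = cand, o = o2, moved = TRUE))
      p <- p / 2
    }
    list(x = cur, o = o, moved = FALSE)
  }
  for (it in seq_len(max_iter)) {
    CNL <- CM %*% N %*% L
    den <- N %*% crossprod(N, CNL)
    facN <- CNL / pmax(den, eps)
    sN <- step(N, facN, function(N2) mnmf_objective(CM, N2, L))
    N <- sN$x; o <- sN$o
    NtCN <- crossprod(N, CM %*% N)
    NtN <- crossprod(N)
    facL <- NtCN / pmax(NtN %*% L %*% NtN, eps)
    sL <- step(L, facL, function(L2) mnmf_objective(CM, N, L2))
    L <- sL$x; o <- sL$o
    trace <- c(trace, o)
    m <- length(trace)
    rel <- abs(trace[m - 1L] - trace[m]) / max(trace[m - 1L], eps)
    if ((!sN$moved && !sL$moved) || rel < tol) { converged <- TRUE; break }
  }
  cn <- sqrt(colSums(N^2)); cn[cn < 1e-12] <- 1
  Nn <- sweep(N, 2L, cn, "/")
  structure(list(N = N, L = L, trace = trace,
                 iterations = length(trace) - 1L, converged = converged,
                 orthogonality = norm(crossprod(Nn) - diag(k), "F")),
            class = "factor_pair")
}

#' @export
print.factor_pair <- function(x, ...) {
  cat(sprintf(
    "<factor_pair> n=%d k=%d, objective %.6g after %d iterations%s\n",
    nrow(x$N), ncol(x$N), x$trace[length(x$trace)], x$iterations,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Harden a factor pair into a partition
#'
#' Assigns instance i to `argmax_j N[i, j]` (ties toward the lowest column);
#' an empty cluster is repaired by moving the instance with the weakest
#' assignment margin into it.
#'
#' @param fp A `factor_pair` from [mnmf_solve()].
#' @return A [partition()] with method `"psa_mnmf"`.
#' @export
harden <- function(fp) {
  N <- fp$N
  k <- ncol(N)
  lab <- max.col(N, ties.method = "first")
  if (length(unique(lab)) < k) {
    best <- N[cbind(seq_len(nrow(N)), lab)]
    second <- apply(N, 1L, function(r) sort(r, decreasing = TRUE)[min(2L, k)])
    margin <- best - second
    sizes <- tabulate(lab, k)
    while (any(sizes == 0L)) {
      empty <- which(sizes == 0L)[1L]
      movable <- which(sizes[lab] > 1L)
      pick <- movable[which.min(margin[movable])]
      lab[pick] <- empty
      margin[pick] <- Inf
      sizes <- tabulate(lab, k)
    }
  }
  partition(lab - 1L, k = k, method = "psa_mnmf")
}

# hard-partition consensus residual || CM - N N^T ||^2 for 1-based labels
hard_objective <- function(CM, lab) {
  U <- outer(lab, lab, `==`) + 0
  sum((CM - U)^2)
}

#' Greedy refinement of a hard consensus partition
#'
#' Final clustering step on the factorization output: single-point
#' reassignment descent on the hard consensus objective
#' `||CM - N N^T||^2` until no move improves it. Deterministic; ties keep
#' the current label.
#'
#' @param cm A `consensus_matrix` or symmetric matrix.
#' @param p A [partition()].
#' @param max_pass Full sweeps cap.
#' @return A refined [partition()].
#' @export
refine_partition <- function(cm, p, max_pass = 50L) {
  CM <- if (inherits(cm, "consensus_matrix")) cm$CM else as.matrix(cm)
  lab <- p$labels + 1L
  k <- p$k
  n <- length(lab)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      if (sum(lab == lab[i]) == 1L) next  # keep k non-empty clusters
      # delta of moving i from its cluster to c: only row/column i changes
      same <- outer(seq_len(k), lab, `==`)[, -i, drop = FALSE] + 0
      cmrow <- CM[i, -i]
      costs <- rowSums((matrix(cmrow, k, n - 1L, byrow = TRUE) - same)^2)
      best <- which.min(costs)
      if (costs[best] < costs[lab[i]] - 1e-12) {
        lab[i] <- best
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  partition(lab - 1L, k = k, method = p$method, seed = p$seed)
}

#' PSA-MNMF consensus of a consensus matrix
#'
#' Multi-restart tri-factorization (`restarts` seeded runs), hardening of
#' each, greedy refinement, and selection of the candidate with the lowest
#' hard consensus objective `||CM - N N^T||^2`.
#'
#' @param cm A `consensus_matrix` or symmetric nonnegative matrix.
#' @param k Number of clusters.
#' @param seed Master seed; restart r uses a seed derived from it.
#' @param restarts Number of restarts (default 5).
#' @param refine Apply [refine_partition()] (default TRUE).
#' @param ... Passed to [mnmf_solve()].
#' @return A [partition()] with attribute `"objective"` (the hard residual)
#'   and `"factor_pair"` (the winning soft solution).
#' @export
mnmf_consensus <- function(cm, k, seed = 1L, restarts = 5L, refine = TRUE,
                           ...) {
  CM <- if (inherits(cm, "consensus_matrix")) cm$CM else as.matrix(cm)
  best <- NULL; best_obj <- Inf; best_fp <- NULL
  for (r in seq_len(restarts)) {
    fp <- mnmf_solve(cm, k, seed = derive_seed(seed, r), ...)
    cand <- harden(fp)
    if (refine) cand <- refine_partition(CM, cand)
    obj <- hard_objective(CM, cand$labels + 1L)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- cand; best_fp <- fp }
  }
  attr(best, "objective") <- best_obj
  attr(best, "factor_pair") <- best_fp
  best
}

#' Full PSA-MNMF consensus from a feature matrix
#'
#' Builds the baseline ensemble, averages it into a co-association matrix,
#' and runs [mnmf_consensus()].
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param methods Baseline methods (>= 2) forming the ensemble.
#' @param k Number of clusters.
#' @param seed Master seed (drives both the ensemble and the factorization).
#' @param restarts MNMF restarts (default 5).
#' @param fit_fn Partitioner passed to [build_ensemble()].
#' @return A [partition()]; attribute `"ensemble"` holds the base ensemble.
#' @export
psa_mnmf_consensus <- function(X, methods = baseline_methods(), k = 2L,
                               seed = 1L, restarts = 5L,
                               fit_fn = fit_partition) {
  ens <- build_ensemble(X, methods, k, seed, fit_fn = fit_fn)
  cm <- average_consensus(ens)
  p <- mnmf_consensus(cm, k, seed = derive_seed(seed, 1000L),
                      restarts = restarts)
  attr(p, "ensemble") <- ens
  p
}
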