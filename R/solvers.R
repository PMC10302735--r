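# Graph-based comparison consensus solvers: CSPA, MCLA, HBGF, HGPA-approx.
# All are deterministic given the ensemble and a seed; ties break toward the
# lowest index.

#' CSPA consensus
#'
#' Treats the averaged co-association matrix as a similarity and cuts an
#' average-linkage agglomeration of `1 - CM` at `k` clusters.
#'
#' @param ens A [partition_ensemble()] (or a `consensus_matrix`).
#' @param k Number of consensus clusters.
#' @return A [partition()] with method `"cspa"`.
#' @export
cspa <- function(ens, k) {
  cm <- as_consensus(ens)
  hc <- stats::hclust(stats::as.dist(1 - cm$CM), method = "average")
  partition(stats::cutree(hc, k) - 1L, k = k, method = "cspa")
}

# binary instance x cluster incidence over every member cluster
hyperedge_incidence <- function(ens) {
  cols <- lapply(ens$partitions, function(p) {
    ks <- sort(unique(p$labels))
    vapply(ks, function(c) as.numeric(p$labels == c), numeric(ens$n))
  })
  do.call(cbind, cols)
}

#' MCLA consensus
#'
#' Clusters the clusters: member clusters become hyperedges (binary
#' indicator columns), pairwise Jaccard similarity between hyperedges is
#' partitioned spectrally into `k` meta-clusters, each meta-cluster is
#' collapsed by averaging its indicators, and every object joins the
#' meta-cluster in which it participates most strongly.
#'
#' @inheritParams cspa
#' @param seed Seed for the spectral meta-clustering.
#' @return A [partition()] with method `"mcla"`.
#' @export
mcla <- function(ens, k, seed = 1L) {
  if (length(ens$partitions) == 1L) {
    p <- ens$partitions[[1L]]
    return(partition(p$labels, p$k, method = "mcla"))
  }
  H <- hyperedge_incidence(ens)
  nh <- ncol(H)
  inter <- crossprod(H)
  sz <- diag(inter)
  uni <- outer(sz, sz, `+`) - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  meta <- if (nh <= k) seq_len(nh) else
    spectral_partition(J, k, seed = derive_seed(seed, 17L))
  # collapse: average indicators per meta-cluster
  A <- vapply(seq_len(max(meta)), function(m)
    rowMeans(H[, meta == m, drop = FALSE]), numeric(ens$n))
  lab <- max.col(A, ties.method = "first")
  lab <- fill_empty_clusters(lab, k, strength = A)
  partition(lab - 1L, k = k, method = "mcla")
}

#' HBGF consensus
#'
#' Bipartite graph of instance vertices and member-cluster vertices, joined
#' where an instance belongs to a cluster; partitioned spectrally (SVD of
#' the degree-normalized incidence) into `k` parts, instances labelled by
#' their part.
#'
#' @inheritParams mcla
#' @return A [partition()] with method `"hbgf"`.
#' @export
hbgf <- function(ens, k, seed = 1L) {
  H <- hyperedge_incidence(ens)
  emb <- bipartite_embedding(H, k)
  lab <- embed_kmeans(emb$inst, k, seed = derive_seed(seed, 23L))
  partition(lab - 1L, k = k, method = "hbgf")
}

#' HGPA consensus (spectral approximation)
#'
#' Approximate minimum-cut k-way hypergraph partition with a size-balance
#' constraint: spectral partitioning of the star-expansion graph followed by
#' a greedy refinement that moves boundary instances to reduce the number of
#' cut hyperedges subject to a part-size cap. Classical HGPA delegates to an
#' external hypergraph partitioner; this native approximation is labelled
#' `"hgpa-approx"`.
#'
#' @inheritParams mcla
#' @return A [partition()] with method `"hgpa-approx"`.
#' @export
hgpa <- function(ens, k, seed = 1L) {
  H <- hyperedge_incidence(ens)
  emb <- bipartite_embedding(H, k)   # star expansion == bipartite graph
  # two initial partitions, each greedily refined; keep the lower cut
  starts <- list(
    embed_kmeans(emb$inst, k, seed = derive_seed(seed, 29L)),
    cspa(ens, k)$labels + 1L)
  cand <- lapply(starts, function(lab) balance_refine(H, lab, k))
  cuts <- vapply(cand, function(lab) hyperedge_cut(H, lab), numeric(1))
  partition(cand[[which.min(cuts)]] - 1L, k = k, method = "hgpa-approx")
}

# hyperedges cut by a labelling (hyperedge spans > 1 part)
hyperedge_cut <- function(H, lab) {
  sum(vapply(seq_len(ncol(H)), function(j) {
    members <- lab[H[, j] > 0]
    length(unique(members)) > 1L
  }, logical(1)))
}

balance_refine <- function(H, lab, k, max_pass = 10L) {
  n <- length(lab)
  cap <- ceiling(1.25 * n / k)
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    cut0 <- hyperedge_cut(H, lab)
    for (i in seq_len(n)) {
      sizes <- tabulate(lab, k)
      for (c in seq_len(k)) {
        if (c == lab[i] || sizes[c] >= cap) next
        if (sizes[lab[i]] <= 1L) next
        l2 <- lab; l2[i] <- c
        cut2 <- hyperedge_cut(H, l2)
        if (cut2 < cut0) { lab <- l2; cut0 <- cut2; moved <- TRUE }
      }
    }
    # ensure k non-empty parts
    sizes <- tabulate(lab, k)
    while (any(sizes == 0L)) {
      empty <- which(sizes == 0L)[1L]
      donor <- which.max(sizes)
      i <- which(lab == donor)[1L]
      lab[i] <- empty
      sizes <- tabulate(lab, k)
    }
    if (!moved) break
  }
  lab
}

# ---- shared spectral utilities ---------------------------------------

# normalized-Laplacian spectral partition of a symmetric affinity matrix
spectral_partition <- function(W, k, seed = 1L) {
  n <- nrow(W)
  if (k >= n) return(seq_len(n))
  d <- rowSums(W)
  d[d < 1e-12] <- 1e-12
  S <- W / sqrt(d %o% d)
  ev <- eigen(S, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  embed_kmeans(U, k, seed)
}

# SVD embedding of a bipartite incidence matrix (instances x clusters)
bipartite_embedding <- function(H, k) {
  d1 <- rowSums(H); d2 <- colSums(H)
  d1[d1 < 1e-12] <- 1e-12; d2[d2 < 1e-12] <- 1e-12
  A <- H / sqrt(d1) / rep(sqrt(d2), each = nrow(H))
  sv <- svd(A, nu = min(k, ncol(A)), nv = 0)
  list(inst = sv$u[, seq_len(min(k, ncol(sv$u))), drop = FALSE])
}

# row-normalized k-means on an eigen/singular embedding
embed_kmeans <- function(U, k, seed = 1L) {
  nrm <- sqrt(rowSums(U^2)); nrm[nrm < 1e-12] <- 1
  U <- U / nrm
  if (nrow(unique(round(U, 10))) < k) {
    # degenerate embedding: group identical rows, then pad deterministically
    key <- apply(round(U, 10), 1L, paste, collapse = ",")
    lab <- as.integer(factor(key, levels = unique(key)))
    return(fill_empty_clusters(pmin(lab, k), k))
  }
  set.seed(seed)
  # Lloyd tolerates the duplicate rows common in these embeddings; an
  # empty-cluster outcome is repaired deterministically afterwards
  lab <- suppressWarnings(
    stats::kmeans(U, centers = k, nstart = 20L, iter.max = 200L,
                  algorithm = "Lloyd")$cluster)
  fill_empty_clusters(lab, k)
}

# guarantee k non-empty clusters (1-based labels); the weakest-margin
# instance of the largest cluster seeds each missing one
fill_empty_clusters <- function(lab, k, strength = NULL) {
  sizes <- tabulate(lab, k)
  while (any(sizes == 0L)) {
    empty <- which(sizes == 0L)[1L]
    donor <- which.max(sizes)
    idx <- which(lab == donor)
    pick <- if (!is.null(strength))
      idx[which.min(strength[cbind(idx, lab[idx])])] else idx[length(idx)]
    lab[pick] <- empty
    sizes <- tabulate(lab, k)
  }
  lab
}

#' Run a named consensus solver
#'
#' Dispatcher over the five solvers sharing the ensemble interface.
#'
#' @param ens A [partition_ensemble()].
#' @param k Number of consensus clusters.
#' @param solver One of `"psa_mnmf"`, `"cspa"`, `"mcla"`, `"hbgf"`, `"hgpa"`.
#' @param seed Seed for stochastic stages.
#' @return A [partition()].
#' @export
consensus_partition <- function(ens, k,
                                solver = c("psa_mnmf", "cspa", "mcla",
                                           "hbgf", "hgpa"),
                                seed = 1L) {
  solver <- match.arg(solver)
  switch(solver,
         psa_mnmf = mnmf_consensus(average_consensus(ens), k, seed = seed),
         cspa = cspa(ens, k),
         mcla = mcla(ens, k, seed = seed),
         hbgf = hbgf(ens, k, seed = seed),
         hgpa = hgpa(ens, k, seed = seed))
}
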