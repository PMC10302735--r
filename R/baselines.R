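# The eight baseline partitioners behind one uniform contract:
# hard labels 0..k-1, deterministic given (X, method, k, seed).
#
# Soft methods (fuzzy C-means, GMM) are hardened by maximum membership /
# posterior; the SOM uses a 1 x k grid with node index = label; the density
# methods (DBSCAN, OPTICS) do not take k, so eps is selected by scanning
# pairwise-distance quantiles until k non-noise clusters emerge, then noise
# and surplus/deficit clusters are repaired to exactly k labels.

#' Fit one baseline partition
#'
#' @param X A `feature_matrix` (or bare numeric matrix) of instances.
#' @param method One of [baseline_methods()].
#' @param k Number of clusters (2 or 3 in the pipeline; any `k <= n` here).
#' @param seed Integer seed; identical calls yield identical labels.
#' @return A [partition()].
#' @export
fit_partition <- function(X, method, k, seed = 1L) {
  method <- match.arg(method, baseline_methods())
  X <- as_feature_rows(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds number of instances", call. = FALSE)
  if (all(apply(X, 2L, stats::sd) < 1e-12))
    stop("degenerate input: all features have zero variance", call. = FALSE)
  set.seed(seed)
  if (k == n) # every instance its own cluster; nothing to optimize
    return(partition(seq_len(n) - 1L, k = k, method = method, seed = seed))
  labels <- switch(method,
    kmeans = stats::kmeans(X, centers = k, nstart = 10L,
                           iter.max = 100L)$cluster,
    fuzzy_cmeans = {
      cm <- e1071::cmeans(X, centers = k, m = 2, iter.max = 200L)
      apply(cm$membership, 1L, which.max)
    },
    som = fit_som(X, k),
    gmm = {
      fit <- mclust::Mclust(X, G = k, modelNames = c("EII", "VII"),
                            verbose = FALSE)
      if (is.null(fit)) stop("GMM fit failed", call. = FALSE)
      fit$classification
    },
    hierarchical = stats::cutree(stats::hclust(stats::dist(X), "ward.D2"), k),
    spectral = fit_spectral(X, k),
    dbscan = fit_density(X, k, flavour = "dbscan"),
    optics = fit_density(X, k, flavour = "optics"))
  partition(as.integer(labels) - 1L, k = k, method = method, seed = seed)
}

as_feature_rows <- function(X) {
  if (inherits(X, "feature_matrix")) X <- X$X
  as.matrix(X)
}

#' Build the baseline ensemble
#'
#' One partition per requested method, each seeded from the master seed by
#' method index so the whole ensemble is reproducible.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param methods Subset of [baseline_methods()], at least 2.
#' @param k Clusters per member.
#' @param seed Master seed.
#' @param fit_fn Partitioner with the [fit_partition()] signature; override
#'   to inject custom ensemble members (e.g. planted or randomized ones in
#'   simulation studies).
#' @return A [partition_ensemble()].
#' @export
build_ensemble <- function(X, methods = baseline_methods(), k = 2L,
                           seed = 1L, fit_fn = fit_partition) {
  if (length(methods) < 2L)
    stop("an ensemble needs at least 2 methods", call. = FALSE)
  parts <- lapply(seq_along(methods), function(i) {
    tryCatch(fit_fn(X, methods[i], k, derive_seed(seed, i)),
             error = function(e)
               stop(sprintf("baseline '%s' failed: %s", methods[i],
                            conditionMessage(e)), call. = FALSE))
  })
  partition_ensemble(parts)
}

# ---- method internals -------------------------------------------------

# 1 x k batch SOM; label = nearest code vector.
fit_som <- function(X, k) {
  grid <- class::somgrid(xdim = 1L, ydim = k, topo = "rectangular")
  sm <- class::batchSOM(X, grid, radii = c(rep(1, 3), rep(0, 6)))
  codes <- sm$codes
  d <- outer(rowSums(X^2), rowSums(codes^2), "+") - 2 * X %*% t(codes)
  max.col(-d, ties.method = "first")
}

# Gaussian affinity with median-distance bandwidth (sigma = 1/(2 h^2)).
fit_spectral <- function(X, k) {
  h <- stats::median(stats::dist(X))
  if (h < 1e-12) h <- 1
  res <- kernlab::specc(X, centers = k, kernel = "rbfdot",
                        kpar = list(sigma = 1 / (2 * h^2)))
  as.integer(res@.Data)
}

# DBSCAN / OPTICS with repair to exactly k clusters (MinPts = 5).
fit_density <- function(X, k, flavour, min_pts = 5L) {
  D <- as.matrix(stats::dist(X))
  qs <- stats::quantile(D[upper.tri(D)],
                        probs = exp(seq(log(0.02), log(0.98),
                                        length.out = 40L)))
  best_lab <- NULL; best_gap <- Inf
  for (eps in unique(qs)) {
    lab <- if (flavour == "dbscan") dbscan_labels(D, eps, min_pts)
           else optics_labels(D, eps, min_pts)
    ncl <- length(setdiff(unique(lab), 0L))
    if (ncl == 0L) next
    gap <- abs(ncl - k)
    if (gap < best_gap) { best_gap <- gap; best_lab <- lab }
    if (gap == 0L) break
  }
  if (is.null(best_lab)) best_lab <- rep(1L, nrow(D))
  repair_to_k(X, best_lab, k)
}

# classic DBSCAN from a distance matrix; 0 = noise
dbscan_labels <- function(D, eps, min_pts) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  lab <- rep(0L, n); cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i; lab[i] <- cl
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (core[j]) {
        new <- nb[[j]][lab[nb[[j]]] == 0L]
        lab[new] <- cl
        queue <- c(queue, new[core[new]])
      }
    }
  }
  lab
}

# OPTICS reachability ordering, then a DBSCAN-style cut at eps
optics_labels <- function(D, eps, min_pts) {
  n <- nrow(D)
  core_dist <- apply(D, 1L, function(d) sort(d)[min_pts])
  reach <- rep(Inf, n); processed <- rep(FALSE, n)
  order_out <- integer(0)
  seeds <- integer(0)
  for (start in seq_len(n)) {
    if (processed[start]) next
    seeds <- start; reach[start] <- Inf
    while (length(seeds)) {
      i <- seeds[which.min(reach[seeds])]
      seeds <- setdiff(seeds, i)
      processed[i] <- TRUE
      order_out <- c(order_out, i)
      if (core_dist[i] <= eps) {
        nb <- which(D[i, ] <= eps & !processed)
        newreach <- pmax(core_dist[i], D[i, nb])
        upd <- newreach < reach[nb]
        reach[nb[upd]] <- newreach[upd]
        seeds <- union(seeds, nb)
      }
    }
  }
  # cut the reachability profile: a jump above eps starts a new cluster
  lab <- rep(0L, n); cl <- 0L
  for (pos in seq_along(order_out)) {
    i <- order_out[pos]
    if (reach[i] > eps) {
      if (core_dist[i] <= eps) { cl <- cl + 1L; lab[i] <- cl }
      # else noise
    } else {
      if (cl == 0L) cl <- 1L
      lab[i] <- cl
    }
  }
  lab
}

# force exactly k non-empty clusters: merge nearest centroids while too
# many, split the largest (2-means) while too few, then assign noise to the
# nearest recovered centroid
repair_to_k <- function(X, lab, k) {
  relab <- function(lab) { u <- setdiff(sort(unique(lab)), 0L)
                           match(lab, u, nomatch = 0L) }
  lab <- relab(lab)
  centroid <- function(cl) colMeans(X[lab == cl, , drop = FALSE])
  while (length(setdiff(unique(lab), 0L)) > k) {
    cls <- setdiff(sort(unique(lab)), 0L)
    cents <- t(vapply(cls, centroid, numeric(ncol(X))))
    dmat <- as.matrix(stats::dist(cents)); diag(dmat) <- Inf
    ij <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
    lab[lab == cls[max(ij)]] <- cls[min(ij)]
    lab <- relab(lab)
  }
  while (length(setdiff(unique(lab), 0L)) < k) {
    cls <- setdiff(sort(unique(lab)), 0L)
    if (!length(cls)) { lab[] <- 1L; cls <- 1L }
    sizes <- vapply(cls, function(c) sum(lab == c), integer(1))
    big <- cls[which.max(sizes)]
    idx <- which(lab == big)
    if (length(idx) < 2L) break
    km <- stats::kmeans(X[idx, , drop = FALSE], centers = 2L, nstart = 5L)
    lab[idx[km$cluster == 2L]] <- max(cls) + 1L
    lab <- relab(lab)
  }
  if (any(lab == 0L)) {
    cls <- setdiff(sort(unique(lab)), 0L)
    cents <- t(vapply(cls, centroid, numeric(ncol(X))))
    for (i in which(lab == 0L)) {
      d <- colSums((t(cents) - X[i, ])^2)
      lab[i] <- cls[which.min(d)]
    }
  }
  lab
}
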