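# Shared fixtures and independent oracles, all built in code.

# two well-separated Gaussian blobs (separation >> sigma)
make_blobs <- function(n = 60L, d = 2L, sep = 10, sigma = 1, k = 2L,
                       seed = 42L) {
  set.seed(seed)
  per <- n %/% k
  X <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(stats::rnorm(per * d, mean = (c - 1L) * sep, sd = sigma), per, d)))
  list(X = X, truth = rep(seq_len(k) - 1L, each = per))
}

# tiny deterministic cohort for io / pipeline structure tests
make_tiny_cohort <- function(n_subjects = 2L, device = "wearable",
                             seed = 5L, duration_s = 1.5) {
  generate_cohort(cohort_spec(
    n_subjects = n_subjects, device = device, duration_s = duration_s,
    seed = seed))
}

# brute-force minimum of ||CM - N N^T||^2 over all hard partitions of n
# instances into exactly k non-empty clusters (independent enumeration
# oracle; counts each labelling once per assignment vector)
enum_hard_minimum <- function(CM, k) {
  n <- nrow(CM)
  best <- Inf
  g <- rep(0L, n)
  repeat {
    if (length(unique(g)) == k) {
      U <- outer(g, g, `==`) + 0
      best <- min(best, sum((CM - U)^2))
    }
    i <- 1L
    while (i <= n) {
      g[i] <- g[i] + 1L
      if (g[i] < k) break
      g[i] <- 0L; i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# direct contingency-table NMI oracle (natural logs, arithmetic mean)
oracle_nmi <- function(x, y) {
  n <- length(x)
  tab <- table(x, y)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- H(rowSums(tab) / n); hy <- H(colSums(tab) / n)
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0)
      mi <- mi + pij * log(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
  }
  2 * mi / (hx + hy)
}

# amplitude of a sinusoid at frequency f in series x (least squares fit)
fit_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1L) / fs
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}

# random orthonormal 3x3 matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

random_partition <- function(n, k, seed) {
  set.seed(seed)
  partition(c(seq_len(k) - 1L, sample(0:(k - 1L), n - k, TRUE))[sample(n)],
            k)
}
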