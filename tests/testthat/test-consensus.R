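# Co-association machinery and the four graph-based comparison solvers.

test_that("connectivity matrices are forced by the definition", {
  expect_equal(connectivity(partition(c(0, 0, 1, 1), 2)),
               rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                     c(0, 0, 1, 1), c(0, 0, 1, 1)))
  expect_equal(connectivity(partition(rep(0, 4), 1)), matrix(1L, 4, 4))
  expect_equal(connectivity(partition(0:3, 4)), diag(4) + 0L)
})

test_that("averaged consensus matrix and dispersion match brute force", {
  p1 <- partition(c(0, 0, 1), 2)
  p2 <- partition(c(0, 1, 1), 2)
  cm <- average_consensus(partition_ensemble(list(p1, p2)))
  expect_equal(cm$CM, rbind(c(1, .5, 0), c(.5, 1, .5), c(0, .5, 1)))

  # dispersion by direct double summation
  Ms <- list(connectivity(p1), connectivity(p2))
  disp <- mean(vapply(Ms, function(M) sum((M - cm$CM)^2), numeric(1)))
  expect_equal(cm$dispersion, disp)
  expect_equal(cm$dispersion, 1)   # 4 disagreeing entries x 0.25, per member

  # identical members: CM equals the shared connectivity, dispersion 0
  cm0 <- average_consensus(partition_ensemble(list(p1, p1)))
  expect_equal(cm0$CM, connectivity(p1) + 0)
  expect_equal(cm0$dispersion, 0)

  # entries lie on the grid {j/T}
  ens <- generate_toy_ensemble(20L, 2L, 0.7, T = 4L, seed = 8L)
  cmg <- average_consensus(ens)
  expect_true(all(abs(cmg$CM * 4 - round(cmg$CM * 4)) < 1e-12))
})

test_that("partition distance is a label-invariant pseudometric", {
  p1 <- partition(c(0, 0, 1), 2)
  p2 <- partition(c(0, 1, 1), 2)
  expect_equal(partition_distance(p1, p1), 0)
  expect_equal(partition_distance(p1, p2), 4)  # ordered pairs (1,2),(2,3)
  # invariant to relabeling p2
  p2r <- partition(1 - c(0, 1, 1), 2)
  expect_equal(partition_distance(p1, p2r), 4)
  # symmetry + triangle inequality on random triples
  for (s in 1:20) {
    ps <- lapply(1:3, function(i) random_partition(12L, 3L, s * 10 + i))
    d12 <- partition_distance(ps[[1]], ps[[2]])
    d21 <- partition_distance(ps[[2]], ps[[1]])
    d13 <- partition_distance(ps[[1]], ps[[3]])
    d23 <- partition_distance(ps[[2]], ps[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
  }
})

test_that("every solver recovers a unanimous ensemble and ignores label permutations", {
  ens <- generate_toy_ensemble(30L, 3L, 1, T = 5L, seed = 4L)
  truth <- attr(ens, "truth")
  expect_equal(average_consensus(ens)$dispersion, 0)
  solvers <- c("psa_mnmf", "cspa", "mcla", "hbgf", "hgpa")
  for (s in solvers) {
    p <- consensus_partition(ens, 3L, s, seed = 2L)
    expect_equal(adjusted_rand(p$labels, truth), 1, info = s)
  }
  # permuting one member's labels changes nothing downstream
  ens2 <- generate_toy_ensemble(24L, 2L, 0.75, T = 5L, seed = 14L)
  perm <- ens2
  perm$partitions[[2]] <- partition(1L - perm$partitions[[2]]$labels, 2L,
                                    method = "permuted")
  for (s in solvers) {
    a <- consensus_partition(ens2, 2L, s, seed = 5L)
    b <- consensus_partition(perm, 2L, s, seed = 5L)
    expect_equal(adjusted_rand(a$labels, b$labels), 1, info = s)
  }
})

test_that("cspa agglomerates the tied 3-point consensus as hand-derived", {
  ens <- partition_ensemble(list(partition(c(0, 0, 1), 2),
                                 partition(c(0, 1, 1), 2)))
  p <- cspa(ens, 2)
  # ties: {1,2},{3} or {1},{2,3}
  ok <- identical(p$labels, c(0L, 0L, 1L)) ||
        identical(p$labels, c(0L, 1L, 1L))
  expect_true(ok)
})

test_that("mcla collapses hyperedges sensibly", {
  # single member: collapse is the identity
  one <- partition_ensemble(list(partition(c(0, 0, 1, 1, 2), 3)))
  expect_equal(adjusted_rand(mcla(one, 3)$labels, c(0, 0, 1, 1, 2)), 1)

  # two clean members + one corrupted: majority structure, checked against
  # the brute-force best k=2 partition of the consensus matrix
  truth <- c(0L, 0L, 0L, 1L, 1L, 1L)
  ens <- partition_ensemble(list(
    partition(truth, 2), partition(truth, 2),
    partition(c(0L, 1L, 0L, 1L, 0L, 1L), 2)))
  cm <- average_consensus(ens)
  p <- mcla(ens, 2)
  U <- outer(p$labels, p$labels, `==`) + 0
  expect_equal(sum((cm$CM - U)^2), enum_hard_minimum(cm$CM, 2),
               tolerance = 1e-9)
  expect_equal(adjusted_rand(p$labels, truth), 1)
})

test_that("hbgf incidence has the documented shape and agrees with cspa at dispersion zero", {
  ens <- generate_toy_ensemble(15L, 2L, 1, T = 4L, seed = 6L)
  H <- psamnmf:::hyperedge_incidence(ens)
  expect_equal(dim(H), c(15L, 8L))   # n x sum_t k_t
  a <- hbgf(ens, 2L, seed = 3L)
  b <- cspa(ens, 2L)
  expect_equal(adjusted_rand(a$labels, b$labels), 1)
})

test_that("hgpa yields k non-empty parts and cuts no more hyperedges than cspa", {
  for (s in 1:5) {
    ens <- generate_toy_ensemble(24L, 2L, 0.7, T = 5L, seed = s)
    H <- psamnmf:::hyperedge_incidence(ens)
    p <- hgpa(ens, 2L, seed = s)
    expect_equal(length(unique(p$labels)), 2L)
    cut_h <- psamnmf:::hyperedge_cut(H, p$labels + 1L)
    cut_c <- psamnmf:::hyperedge_cut(H, cspa(ens, 2L)$labels + 1L)
    expect_lte(cut_h, cut_c)
  }
})

test_that("anmi matches the entropy oracle and its boundary cases", {
  ens <- generate_toy_ensemble(20L, 2L, 1, T = 3L, seed = 9L)
  shared <- ens$partitions[[1]]
  expect_equal(anmi(shared, ens), 1)

  # independent splits share no information
  ind <- partition_ensemble(list(partition(c(0, 1, 0, 1), 2)))
  expect_equal(anmi(partition(c(0, 0, 1, 1), 2), ind), 0)

  # mixed ensemble: mean of pairwise NMIs from the contingency oracle
  p1 <- random_partition(30L, 3L, 71L)
  p2 <- random_partition(30L, 2L, 72L)
  cand <- random_partition(30L, 2L, 73L)
  ens2 <- partition_ensemble(list(p1, p2))
  expect_equal(anmi(cand, ens2),
               mean(c(oracle_nmi(cand$labels, p1$labels),
                      oracle_nmi(cand$labels, p2$labels))),
               tolerance = 1e-12)
})

test_that("ensemble label CSV round-trips", {
  ens <- generate_toy_ensemble(10L, 2L, 0.8, T = 3L, seed = 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  for (i in 1:3)
    expect_identical(back$partitions[[i]]$labels, ens$partitions[[i]]$labels)
})
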