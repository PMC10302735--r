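# Trunk displacement, cluster labeling, FMA mapping, metrics.

# bare trial with a controllable trunk channel
trunk_trial <- function(t8_xyz, device = "wearable") {
  prof <- device_profile(device)
  n <- nrow(t8_xyz)
  channels <- setNames(lapply(prof$channels, function(ch) {
    m <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    m[, 1] <- seq_len(n) * 1e-3   # non-degenerate
    m
  }), prof$channels)
  for (ch in prof$trunk_channels) channels[[ch]] <- t8_xyz
  motion_trial("S1", device, "cup", 1L, channels)
}

test_that("trunk displacement follows the 10-sample baseline convention", {
  # stationary trunk -> zero everywhere
  td <- trunk_displacement(trunk_trial(matrix(5, 40, 3)))
  expect_equal(td$series, rep(0, 40))
  expect_equal(td$trial_mean, 0)

  # +2 mm x-step after the baseline window
  m <- matrix(0, 40, 3)
  m[11:40, 1] <- 2
  td <- trunk_displacement(trunk_trial(m))
  expect_equal(td$series[11:40], rep(2, 30))
  expect_equal(td$series[1:10], rep(0, 10))

  # linear drift: hand-computed mean of |0.5 t - baseline|
  n <- 100L
  m <- matrix(0, n, 3)
  m[, 1] <- 0.5 * (0:(n - 1L))
  base <- mean(0.5 * (0:9))
  expect_equal(trunk_displacement(trunk_trial(m))$trial_mean,
               mean(abs(0.5 * (0:(n - 1L)) - base)))

  # signed convention cancels oscillatory sway, absolute does not
  mo <- matrix(0, 60, 3)
  mo[, 2] <- c(rep(0, 10), rep(c(-3, 3), 25))
  expect_gt(trunk_displacement(trunk_trial(mo))$trial_mean, 1)
  expect_lt(abs(trunk_displacement(trunk_trial(mo),
                                   signed_sum = TRUE)$trial_mean), 0.2)

  # camera: the four trunk markers are averaged
  cam <- trunk_trial(m[1:50, ], device = "camera")
  cam$channels[["sternum_upper"]][, 1] <-
    cam$channels[["sternum_upper"]][, 1] + 100  # constant offset, no effect
  tdc <- trunk_displacement(cam)
  expect_equal(tdc$trial_mean,
               mean(abs(0.5 * (0:49) - mean(0.5 * (0:9)))), tolerance = 1e-9)
})

test_that("clusters are ranked by mean displacement, ties by id", {
  p <- partition(c(0, 0, 1, 1), 2)
  lab <- label_clusters(p, c(10, 10, 50, 50))
  expect_equal(unname(lab$cluster_class), c("non-severe", "severe"))

  p3 <- partition(c(0, 0, 1, 1, 2, 2), 3)
  lab3 <- label_clusters(p3, c(5, 5, 20, 20, 60, 60))
  expect_equal(unname(lab3$cluster_class), c("non-severe", "mild", "severe"))

  # equal means: lower cluster id ranked less severe
  labt <- label_clusters(p, c(7, 7, 7, 7))
  expect_equal(unname(labt$cluster_class), c("non-severe", "severe"))

  # invariant to cluster-id permutation of the input partition
  pperm <- partition(1 - p$labels, 2)
  labp <- label_clusters(pperm, c(10, 10, 50, 50))
  expect_equal(as.character(labp$classes), as.character(lab$classes))

  expect_error(label_clusters(p, c(1, 2, 3)), "aligned")
})

test_that("monotonicity: inflating the severe cluster cannot demote it", {
  set.seed(31)
  p <- random_partition(30L, 2L, 31L)
  td <- runif(30, 0, 20)
  lab <- label_clusters(p, td)
  severe_id <- as.integer(names(which(lab$cluster_class == "severe")))
  td2 <- td + 25 * (p$labels == severe_id)
  lab2 <- label_clusters(p, td2)
  expect_equal(lab2$cluster_class[[as.character(severe_id)]], "severe")
})

test_that("FMA banding uses the half-open severe-below-29 rule", {
  expect_equal(as.character(fma_to_severity(17L, 2L)), "severe")
  expect_equal(as.character(fma_to_severity(29L, 2L)), "non-severe")
  expect_equal(as.character(fma_to_severity(46L, 3L)), "non-severe")
  expect_equal(as.character(fma_to_severity(35L, 3L)), "mild")
  expect_equal(as.character(fma_to_severity(0L, 3L)), "severe")
  expect_error(fma_to_severity(67L, 2L), "range")
})

test_that("metrics reproduce the hand-worked confusion example", {
  truth <- c("severe", "severe", "non-severe", "non-severe")
  pred <- c("severe", "non-severe", "non-severe", "non-severe")
  m <- evaluate_severity(pred, truth)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(m$f_score, 0.5 * (2 / 3) + 0.5 * (4 / 5))

  perfect <- evaluate_severity(truth, truth)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall",
                                "f_score")]),
               c(accuracy = 1, precision = 1, recall = 1, f_score = 1))
})

test_that("weighted recall equals accuracy and metrics stay in [0,1]", {
  classes <- c("non-severe", "mild", "severe")
  for (s in 1:50) {
    set.seed(s)
    n <- sample(5:60, 1)
    truth <- sample(classes, n, TRUE)
    pred <- sample(classes, n, TRUE)
    m <- evaluate_severity(pred, truth)
    expect_equal(m$recall, m$accuracy)
    vals <- unlist(m[c("accuracy", "precision", "recall", "f_score")])
    expect_true(all(vals >= 0 & vals <= 1))
    # instance order is irrelevant
    o <- sample(n)
    m2 <- evaluate_severity(pred[o], truth[o])
    expect_equal(m2$f_score, m$f_score)
  }
})
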