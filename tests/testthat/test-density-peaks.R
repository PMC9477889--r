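test_that("pairwise distances follow the squared-Euclidean convention", {
  Y <- rbind(c(0, 0), c(3, 4))
  D <- pairwise_distances(Y)
  expect_equal(D[1, 2], 25)
  expect_equal(diag(D), c(0, 0))
  expect_equal(pairwise_distances(Y, squared = FALSE)[1, 2], 5)

  set.seed(7)
  Yr <- matrix(rnorm(30), 10, 3)
  Dr <- pairwise_distances(Yr)
  expect_equal(Dr, t(Dr))
  expect_equal(pairwise_distances(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
})

test_that("cutoff distance ranks the sorted pair distances", {
  set.seed(11)
  Y <- matrix(rnorm(60), 20, 3)
  D <- pairwise_distances(Y)
  ds <- sort(D[upper.tri(D)])
  # M = 190 pairs, round(190 * 0.02) = round(3.8) = 4th smallest
  expect_equal(cutoff_distance(D, 0.02), ds[4])
  # squared-distance homogeneity: scaling Y by c scales dc by c^2
  expect_equal(cutoff_distance(pairwise_distances(3 * Y), 0.02),
               9 * cutoff_distance(D, 0.02))
  # rank clamps at 1 for tiny t
  expect_warning(dc_min <- cutoff_distance(D, 1e-4), "outside")
  expect_equal(dc_min, ds[1])
  # points basis uses n instead of the pair count
  expect_equal(cutoff_distance(D, 0.02, rank_basis = "points"),
               ds[max(1, round(20 * 0.02))])
})

test_that("local density follows the shifted Gaussian-kernel formula", {
  D <- matrix(c(0, 4, 4, 0), 2)
  expect_equal(local_density(D, dc = 4), rep(exp(-1) - 1, 2))
  # n coincident points: rho = n - 2 with the literal shift
  n <- 6
  D0 <- matrix(0, n, n)
  expect_equal(local_density(D0, dc = 1), rep(n - 2, n))
  # the shift never changes the density ordering (checked away from
  # underflow, where subtracting 1 would absorb sub-epsilon differences)
  set.seed(3)
  Dr <- pairwise_distances(matrix(rnorm(36), 12, 3))
  dc <- stats::median(Dr)
  expect_equal(order(local_density(Dr, dc, shift = TRUE)),
               order(local_density(Dr, dc, shift = FALSE)))
  expect_error(local_density(Dr, dc = 0), "positive")
})

test_that("delta and the uphill neighbor follow the two-branch rule", {
  # 1-D points {0, 1, 3} with decreasing densities (squared distances)
  Y <- matrix(c(0, 1, 3))
  D <- pairwise_distances(Y)
  rho <- c(3, 2, 1)
  dn <- delta_neighbor(D, rho)
  expect_equal(dn$delta, c(9, 1, 4))   # max for the summit, min-to-denser else
  expect_equal(dn$n_up, c(1L, 1L, 2L))
  # brute-force oracle on random instances
  for (s in 1:5) {
    set.seed(s)
    Yr <- matrix(rnorm(30), 10, 3)
    Dr <- pairwise_distances(Yr)
    rr <- local_density(Dr, cutoff_distance(Dr, 0.015))
    ref <- dp_reference(Yr, 0.015, 2)
    got <- delta_neighbor(Dr, rr)
    expect_equal(got$delta, ref$delta)
    expect_equal(got$n_up, ref$n_up)
  }
})

test_that("the center-selection index and center picking are deterministic", {
  expect_equal(dp_index(2, 3), 6)
  expect_equal(dp_index(c(0, 2), c(5, 3)), c(0, 6))
  expect_equal(select_centers(c(5, 1, 4, 9), 2), c(4L, 1L))
  expect_equal(select_centers(c(1, 1), 2), c(1L, 2L))
  # tied lambda: larger rho wins, then lower index
  expect_equal(select_centers(c(3, 3, 1), 1, rho = c(1, 2, 9)), 2L)
  expect_equal(select_centers(c(3, 3, 1), 1, rho = c(2, 2, 9)), 1L)
  expect_error(select_centers(1:3, 4), "exceeds")
})

test_that("labels propagate down the density ordering from the centers", {
  # chain c <- b <- a where a is a center
  rho <- c(3, 2, 1)
  n_up <- c(1L, 1L, 2L)
  expect_equal(assign_labels(rho, n_up, centers = 1L), c(1L, 1L, 1L))
  # centers keep their own labels
  expect_equal(assign_labels(rho, n_up, centers = c(1L, 2L)), c(1L, 2L, 2L))
  # orphan (self-pointing non-center) goes to the nearest center
  D <- pairwise_distances(matrix(c(0, 5, 6)))
  expect_warning(
    L <- assign_labels(c(9, 2, 1), c(1L, 1L, 2L), centers = c(2L, 3L), D = D),
    "not a center")
  expect_equal(L[1], 1L)
  # random instances against the pointer-following oracle
  for (s in 1:5) {
    set.seed(100 + s)
    Yr <- matrix(rnorm(24), 8, 3)
    ref <- dp_reference(Yr, 0.015, 3)
    dp <- suppressWarnings(dp_cluster(Yr, 0.015, 3))
    expect_equal(dp$labels, ref$labels)
  }
})

test_that("dp_cluster recovers well-separated blobs and is deterministic", {
  blobs <- make_blobs(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      n_each = 50, sd = 0.05, seed = 42)
  dp <- dp_cluster(blobs$Y, t = 0.015, K = 3)
  expect_equal(as.numeric(sorting_accuracy(dp$labels, blobs$labels)), 1)
  expect_equal(sort(unique(dp$labels)), 1:3)
  # determinism
  dp2 <- dp_cluster(blobs$Y, t = 0.015, K = 3)
  expect_identical(dp, dp2)
  # n == K: every point its own cluster
  Y <- matrix(rnorm(12), 4, 3)
  expect_equal(sort(dp_cluster(Y, K = 4)$labels), 1:4)
})

test_that("selected centers dominate non-centers in the DP index", {
  for (s in 1:10) {
    set.seed(200 + s)
    Y <- matrix(rnorm(3 * sample(6:12, 1)), ncol = 3)
    dp <- suppressWarnings(dp_cluster(Y, t = 0.015, K = 3))
    st <- dp$state
    expect_true(min(st$lam[st$centers]) >= max(st$lam[-st$centers]))
    expect_equal(length(unique(dp$labels)), 3L)
  }
})
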