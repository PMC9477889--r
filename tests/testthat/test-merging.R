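test_that("compactness, separation and similarity follow their definitions", {
  expect_equal(compactness(rbind(c(0, 0), c(2, 0)), c(1, 1), rbind(c(1, 0))), 1)
  expect_equal(compactness(rbind(c(3, 4)), 1, rbind(c(3, 4))), 0)
  # translation invariance
  Y <- rbind(c(0, 0), c(2, 0), c(5, 5))
  cp1 <- compactness(Y, c(1, 1, 2), rbind(c(1, 0), c(5, 5)))
  cp2 <- compactness(sweep(Y, 2, c(7, -3), `+`), c(1, 1, 2),
                     rbind(c(8, -3), c(12, 2)))
  expect_equal(cp1, cp2)

  SP <- separation(rbind(c(0, 0), c(3, 4)))
  expect_equal(SP[1, 2], 5)
  expect_equal(SP, t(SP))
  expect_equal(separation(matrix(c(0, 1, 3))),
               rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)))

  R <- cluster_similarity(c(1, 2), separation(rbind(c(0, 0), c(6, 0))))
  expect_equal(R[1, 2], 0.5)
  expect_equal(cluster_similarity(c(0, 0), separation(rbind(c(0, 0), c(2, 0))))[1, 2], 0)
  # ratio is invariant to a global rescale of the feature space
  Y3 <- rbind(c(0, 0), c(1, 0), c(4, 0), c(5, 0))
  L3 <- c(1, 1, 2, 2)
  cen <- rbind(c(0.5, 0), c(4.5, 0))
  r1 <- cluster_similarity(compactness(Y3, L3, cen), separation(cen))
  r2 <- cluster_similarity(compactness(3 * Y3, L3, 3 * cen), separation(3 * cen))
  expect_equal(r1[1, 2], r2[1, 2])
  # coincident centers flag infinite similarity
  expect_equal(cluster_similarity(c(1, 1), matrix(0, 2, 2))[1, 2], Inf)
})

test_that("the merge threshold is alpha times the mean pair similarity", {
  R <- matrix(NA_real_, 3, 3)
  R[upper.tri(R)] <- c(0.5, 0.7, 0.9)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  expect_equal(merge_threshold(R, alpha = 1.6), 1.6 * 0.7)
  expect_equal(merge_threshold(R, alpha = 1.6, denominator = "points",
                               n_points = 100),
               1.6 * sum(c(0.5, 0.7, 0.9)) / (100 * 99 / 2))
  expect_error(merge_threshold(matrix(1), 1.6), "2 clusters")
})

test_that("an over-split blob merges exactly once and far blobs never merge", {
  set.seed(17)
  tight <- matrix(rnorm(100, sd = 0.05), 50, 2)
  far1 <- sweep(matrix(rnorm(100, sd = 0.05), 50, 2), 2, c(10, 0), `+`)
  far2 <- sweep(matrix(rnorm(100, sd = 0.05), 50, 2), 2, c(0, 10), `+`)
  Y <- rbind(far1, far2, tight)
  # the tight blob is split into two random halves -> 4 clusters
  halves <- sample(rep(3:4, 25))
  L <- c(rep(1, 50), rep(2, 50), halves)
  centers <- vapply(1:4, function(k) {
    idx <- which(L == k)
    cen <- colMeans(Y[idx, , drop = FALSE])
    idx[which.min(rowSums(sweep(Y[idx, , drop = FALSE], 2, cen)^2))]
  }, integer(1))
  merged <- merge_clusters(Y, L, centers, alpha = 1.6)
  expect_equal(nrow(merged$report$merges), 1L)
  expect_equal(merged$report$final_K, 3L)
  # the merged pair is the split blob
  expect_equal(length(unique(merged$labels[101:150])), 1L)

  # three well-separated tight blobs: no merges, labels unchanged
  L3 <- c(rep(1, 50), rep(2, 50), rep(3, 50))
  centers3 <- vapply(1:3, function(k) {
    idx <- which(L3 == k)
    cen <- colMeans(Y[idx, , drop = FALSE])
    idx[which.min(rowSums(sweep(Y[idx, , drop = FALSE], 2, cen)^2))]
  }, integer(1))
  merged3 <- merge_clusters(Y, L3, centers3, alpha = 1.6)
  expect_equal(nrow(merged3$report$merges), 0L)
  expect_equal(merged3$labels, L3)
})

test_that("a two-cluster input can never merge under the mean threshold", {
  set.seed(23)
  Y <- rbind(matrix(rnorm(40, sd = 2), 20, 2),
             matrix(rnorm(40, 0.5, sd = 2), 20, 2))  # heavily overlapping
  L <- rep(1:2, each = 20)
  merged <- merge_clusters(Y, L, centers = c(1L, 21L), alpha = 1.6)
  expect_equal(nrow(merged$report$merges), 0L)
  expect_equal(merged$report$final_K, 2L)
})

test_that("every executed merge exceeded that round's threshold and labels stay gapless", {
  set.seed(29)
  Y <- matrix(rnorm(160, sd = 1.5), 80, 2)       # amorphous: merges likely
  dp <- dp_cluster(Y, K = 4)
  merged <- merge_clusters(Y, dp$labels, dp$state$centers)
  rep_ <- merged$report
  if (nrow(rep_$merges) > 0) {
    for (r in seq_len(nrow(rep_$merges))) {
      round_i <- rep_$merges$round[r]
      R <- rep_$R_history[[round_i]]
      expect_true(max(R[upper.tri(R)]) > rep_$Rth_history[round_i] ||
                  any(is.infinite(R[upper.tri(R)])))
    }
  }
  expect_equal(sort(unique(merged$labels)), seq_len(rep_$final_K))
  expect_equal(4L - nrow(rep_$merges), rep_$final_K)
  expect_lte(nrow(rep_$merges), 2L)   # K_init - 2 merges at most
})
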