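#' Cluster compactness
#'
#' Mean (plain, un-squared) Euclidean distance of cluster members to their
#' cluster center. Centers are the density-peaks exemplar coordinates by
#' default; see [merge_clusters()].
#'
#' @param Y `n x d` feature matrix.
#' @param L Labels `1..K`.
#' @param centers_pos `K x d` matrix of center coordinates (row k = center
#'   of cluster k).
#' @return Numeric vector of K compactness values.
#' @examples
#' compactness(rbind(c(0, 0), c(2, 0)), c(1, 1), rbind(c(1, 0)))  # 1
#' @export
compactness <- function(Y, L, centers_pos) {
  Y <- as.matrix(Y)
  centers_pos <- matrix(centers_pos, ncol = ncol(Y))
  K <- nrow(centers_pos)
  vapply(seq_len(K), function(k) {
    Yk <- Y[L == k, , drop = FALSE]
    if (nrow(Yk) == 0) stop("cluster ", k, " is empty")
    mean(sqrt(rowSums(sweep(Yk, 2, centers_pos[k, ])^2)))
  }, numeric(1))
}

#' Cluster separation
#'
#' Euclidean distance between every pair of cluster centers.
#'
#' @param centers_pos `K x d` matrix of center coordinates (K >= 2).
#' @return Symmetric `K x K` matrix with zero diagonal.
#' @export
separation <- function(centers_pos) {
  centers_pos <- as.matrix(centers_pos)
  if (nrow(centers_pos) < 2) stop("need at least 2 centers")
  SP <- as.matrix(stats::dist(centers_pos))
  dimnames(SP) <- NULL
  SP
}

#' Pairwise cluster-similarity ratio
#'
#' `R_ab = (CP_a + CP_b) / SP_ab`: large when two clusters are diffuse
#' relative to the gap between their centers, i.e. likely over-split.
#' Coincident centers (`SP_ab = 0`) give `R_ab = Inf`.
#'
#' @param CP Compactness vector from [compactness()].
#' @param SP Separation matrix from [separation()].
#' @return Symmetric `K x K` matrix; diagonal is `NA` (undefined).
#' @export
cluster_similarity <- function(CP, SP) {
  K <- length(CP)
  stopifnot(nrow(SP) == K)
  R <- outer(CP, CP, `+`) / SP
  R[SP == 0] <- Inf
  diag(R) <- NA_real_
  R
}

#' Merge threshold
#'
#' `Rth = alpha * mean(R)` over the `K(K-1)/2` cluster pairs. The mean
#' construction means no merge can ever fire at `K = 2` when `alpha > 1`:
#' the single pair's threshold is strictly above its own similarity.
#' `denominator = "points"` divides the similarity sum by `n(n-1)/2` with
#' `n` the number of data points instead (an alternative normalization
#' retained for replication; it requires `n_points`).
#'
#' @param R Similarity matrix from [cluster_similarity()].
#' @param alpha Threshold coefficient (> 1; default 1.6).
#' @param denominator `"pairs"` (default) or `"points"`.
#' @param n_points Number of data points, used only for `"points"`.
#' @return Scalar threshold.
#' @examples
#' R <- cluster_similarity(c(1, 1, 1), separation(rbind(0, 1, 3)))
#' merge_threshold(R, alpha = 1.6)
#' @export
merge_threshold <- function(R, alpha = 1.6,
                            denominator = c("pairs", "points"),
                            n_points = NULL) {
  denominator <- match.arg(denominator)
  K <- nrow(R)
  if (is.null(K) || K < 2) stop("need at least 2 clusters")
  vals <- R[upper.tri(R)]
  if (denominator == "pairs") {
    alpha * mean(vals)
  } else {
    if (is.null(n_points)) stop("n_points required for denominator = 'points'")
    alpha * sum(vals) / (n_points * (n_points - 1) / 2)
  }
}

#' Merge over-split clusters until all similarities fall below threshold
#'
#' Iterates: compute compactness, separation, similarity `R` and the
#' threshold `Rth`; find the most similar pair; if its similarity exceeds
#' `Rth` (an infinite similarity from coincident centers merges
#' unconditionally), merge the pair and repeat, otherwise stop. When a
#' pair merges, the larger cluster absorbs the smaller (ties: lower
#' label) and keeps its exemplar as the merged center. The loop fixes the
#' final number of clusters with no user input: with `alpha > 1` it
#' always stops at `K >= 2`, and each round removes exactly one cluster.
#'
#' @param Y `n x d` feature matrix.
#' @param L Labels `1..K` from [dp_cluster()].
#' @param centers Center point indices in label order (cluster k's
#'   exemplar is `centers[k]`).
#' @param alpha Threshold coefficient (default 1.6).
#' @param use_centroid Use cluster means instead of exemplars for both
#'   compactness and separation (default FALSE).
#' @param denominator Passed to [merge_threshold()].
#' @return List with `labels` (relabeled `1..final_K`, no gaps) and
#'   `report` (class `merge_report`): `R_history`, `Rth_history`,
#'   `merges` data frame (`a`, `b`, `round`; labels as of that round),
#'   `final_K`, `centers` (surviving exemplar indices).
#' @export
merge_clusters <- function(Y, L, centers, alpha = 1.6,
                           use_centroid = FALSE, denominator = "pairs") {
  Y <- as.matrix(Y)
  L <- as.integer(L)
  K <- length(centers)
  stopifnot(max(L) <= K, min(L) >= 1)
  if (alpha <= 1) stop("alpha must exceed 1")
  if (alpha <= 1.4)
    warning("alpha = ", alpha, " is at or below the recommended lower bound 1.4")
  R_history <- list(); Rth_history <- numeric(0)
  merges <- data.frame(a = integer(0), b = integer(0), round = integer(0))
  round_i <- 0L
  while (K >= 2) {
    round_i <- round_i + 1L
    centers_pos <- if (use_centroid) {
      matrix(vapply(seq_len(K),
                    function(k) colMeans(Y[L == k, , drop = FALSE]),
                    numeric(ncol(Y))),
             nrow = K, byrow = TRUE)
    } else {
      Y[centers, , drop = FALSE]
    }
    CP <- compactness(Y, L, centers_pos)
    SP <- separation(centers_pos)
    R <- cluster_similarity(CP, SP)
    Rth <- merge_threshold(R, alpha, denominator, n_points = nrow(Y))
    R_history[[round_i]] <- R
    Rth_history[round_i] <- Rth
    # most similar pair; infinities (coincident centers) merge first
    ut <- which(upper.tri(R), arr.ind = TRUE)
    vals <- R[ut]
    best <- which.max(vals)
    if (!(is.infinite(vals[best]) || vals[best] > Rth)) break
    i <- ut[best, 1]; j <- ut[best, 2]
    # absorber a = larger cluster (ties: lower label)
    ni <- sum(L == i); nj <- sum(L == j)
    a <- if (nj > ni) j else i
    b <- if (a == i) j else i
    merges <- rbind(merges, data.frame(a = a, b = b, round = round_i))
    L[L == b] <- a
    L[L > b] <- L[L > b] - 1L
    centers <- centers[-b]
    K <- K - 1L
  }
  report <- structure(list(R_history = R_history,
                           Rth_history = Rth_history,
                           merges = merges, final_K = K,
                           centers = centers),
                      class = "merge_report")
  list(labels = L, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("merge_report: %d merge(s), final K = %d\n",
              nrow(x$merges), x$final_K))
  for (r in seq_len(nrow(x$merges))) {
    cat(sprintf("  round %d: cluster %d absorbed cluster %d (Rth = %.3f)\n",
                x$merges$round[r], x$merges$a[r], x$merges$b[r],
                x$Rth_history[x$merges$round[r]]))
  }
  invisible(x)
}
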