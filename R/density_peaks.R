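# Round half away from zero (the rounding used for the cutoff rank);
# base::round() rounds half to even, which is not what we want here.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Pairwise distance matrix of the feature points
#'
#' The clustering operates on squared Euclidean distances
#' `d_ij = (y_i - y_j)'(y_i - y_j)` by default; `squared = FALSE` gives
#' the plain Euclidean convention of the original density-peaks method.
#'
#' @param Y `n x d` feature matrix.
#' @param squared Use squared distances (default TRUE).
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
pairwise_distances <- function(Y, squared = TRUE) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2) stop("need at least 2 points")
  # accumulate coordinate-wise squared differences in column order: the
  # result is then bitwise-identical to a naive sum((y_i - y_j)^2) loop,
  # so downstream density tie-breaks cannot flip on rounding noise
  D <- matrix(0, nrow(Y), nrow(Y))
  for (j in seq_len(ncol(Y))) D <- D + outer(Y[, j], Y[, j], `-`)^2
  if (!squared) D <- sqrt(D)
  D
}

#' Cutoff distance from the sorted pairwise distances
#'
#' `dc` is a low quantile of the ascending list of the `M = n(n-1)/2`
#' off-diagonal distances: the entry at rank `round(M * t)` (half away
#' from zero, clamped to `[1, M]`). `rank_basis = "points"` instead ranks
#' at `round(n * t)`, the literal small-index reading.
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param t Cutoff-distance index in (0, 1); the rule of thumb is
#'   0.01-0.02 (default 0.015).
#' @param rank_basis `"pairs"` (default) or `"points"`.
#' @return Scalar cutoff distance `dc > 0`.
#' @export
cutoff_distance <- function(D, t = 0.015, rank_basis = c("pairs", "points")) {
  rank_basis <- match.arg(rank_basis)
  if (!(t > 0 && t < 1)) stop("t must lie in (0, 1)")
  if (t < 0.01 || t > 0.02)
    warning("t = ", t, " is outside the usual 0.01-0.02 range")
  ds <- sort(D[upper.tri(D)])
  M <- length(ds)
  base <- if (rank_basis == "pairs") M else nrow(D)
  r <- min(max(round_half_away(base * t), 1), M)
  dc <- ds[r]
  if (dc <= 0) {
    pos <- ds[ds > 0]
    if (length(pos)) {
      dc <- pos[1]
    } else {
      warning("all pairwise distances are zero; using machine epsilon as dc")
      dc <- .Machine$double.eps
    }
  }
  dc
}

#' Gaussian-kernel local density
#'
#' `rho_i = sum_{j != i} exp(-(d_ij/dc)^2) - 1`. The trailing `-1` is a
#' constant shift that leaves the density ordering unchanged but enters
#' the center-selection index `lambda = rho * delta`; `shift = FALSE`
#' drops it.
#'
#' @param D Distance matrix.
#' @param dc Cutoff distance (> 0).
#' @param shift Apply the literal `-1` shift (default TRUE).
#' @return Density per point.
#' @export
local_density <- function(D, dc, shift = TRUE) {
  if (dc <= 0) stop("dc must be positive")
  K <- exp(-(D / dc)^2)
  diag(K) <- 0                   # exclude the j == i term exactly
  rho <- rowSums(K)
  if (shift) rho <- rho - 1
  rho
}

#' Distance to the nearest higher-density point
#'
#' For the global density maximum, `delta` is its largest distance to any
#' point and its neighbor is itself; for every other point, `delta` is
#' the minimum distance to a strictly-higher-density point and `n_up` is
#' that point. Density ties are broken by index (lower index counts as
#' higher), making the density maximum unique.
#'
#' @param D Distance matrix.
#' @param rho Densities from [local_density()].
#' @return List with `delta` and `n_up` (both length n).
#' @export
delta_neighbor <- function(D, rho) {
  n <- length(rho)
  stopifnot(nrow(D) == n)
  ord <- order(-rho, seq_len(n))   # descending density, lower index wins ties
  delta <- numeric(n)
  n_up <- integer(n)
  top <- ord[1]
  delta[top] <- max(D[top, ])
  n_up[top] <- top
  for (r in seq_len(n)[-1]) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1L)]
    dvec <- D[i, higher]
    m <- which.min(dvec)
    delta[i] <- dvec[m]
    n_up[i] <- higher[m]
  }
  list(delta = delta, n_up = n_up)
}

#' Center-selection index
#'
#' `lambda_i = rho_i * delta_i`: large only for points that are both dense
#' and far from any denser point, i.e. cluster centers.
#'
#' @param rho,delta Equal-length numeric vectors.
#' @return Elementwise product.
#' @export
dp_index <- function(rho, delta) {
  stopifnot(length(rho) == length(delta))
  rho * delta
}

#' Select the K cluster centers
#'
#' The K points with the largest index `lambda`, in decreasing order (the
#' first returned center seeds cluster 1). Ties are broken by larger
#' density, then by lower point index.
#'
#' @param lam Index per point from [dp_index()].
#' @param K Number of centers.
#' @param rho Densities, used only for tie-breaking.
#' @return Integer vector of K distinct point indices.
#' @export
select_centers <- function(lam, K, rho = NULL) {
  n <- length(lam)
  if (K > n) stop("K = ", K, " exceeds the number of points (", n, ")")
  if (is.null(rho)) rho <- numeric(n)
  ord <- order(-lam, -rho, seq_len(n))
  ord[seq_len(K)]
}

#' Propagate labels from the centers
#'
#' Centers receive labels `1..K` in the order given (lambda rank). The
#' remaining points are traversed in decreasing density and inherit the
#' label of their nearest higher-density neighbor, which is guaranteed to
#' be labeled already. A degenerate self-pointing non-center (the density
#' maximum when it was not selected) is assigned to its nearest center,
#' with a warning; this requires `D`.
#'
#' @param rho Densities.
#' @param n_up Nearest higher-density neighbor per point.
#' @param centers Center indices in label order.
#' @param D Distance matrix, only needed for the degenerate case.
#' @return Integer label vector in `1..K`.
#' @export
assign_labels <- function(rho, n_up, centers, D = NULL) {
  n <- length(rho)
  L <- integer(n)
  L[centers] <- seq_along(centers)
  ord <- order(-rho, seq_len(n))
  for (i in ord) {
    if (L[i] != 0L) next
    if (n_up[i] == i) {
      if (is.null(D))
        stop("self-pointing non-center encountered and no D supplied")
      warning("density maximum is not a center; assigning it to the nearest center")
      L[i] <- L[centers[which.min(D[i, centers])]]
    } else {
      L[i] <- L[n_up[i]]
    }
  }
  L
}

#' Density-peaks clustering of a feature matrix
#'
#' Runs the full chain: pairwise distances, cutoff distance, densities,
#' higher-density neighbors, center-selection index, K centers, label
#' propagation. Deterministic for a fixed input.
#'
#' @param Y `n x d` feature matrix (`n >= K`).
#' @param t Cutoff-distance index (default 0.015).
#' @param K Number of clusters to seed (default 4).
#' @param squared Squared-distance convention (default TRUE).
#' @param shift Literal `-1` density shift (default TRUE).
#' @param rank_basis Rank basis for `dc`, see [cutoff_distance()].
#' @return List with `labels` and `state` (fields `D`, `dc`, `rho`,
#'   `delta`, `n_up`, `lam`, `centers`).
#' @examples
#' set.seed(1)
#' Y <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
#' table(dp_cluster(Y, K = 2)$labels)
#' @export
dp_cluster <- function(Y, t = 0.015, K = 4, squared = TRUE, shift = TRUE,
                       rank_basis = "pairs") {
  Y <- as.matrix(Y)
  if (nrow(Y) < K) stop("need at least K points")
  D <- pairwise_distances(Y, squared = squared)
  dc <- cutoff_distance(D, t, rank_basis = rank_basis)
  rho <- local_density(D, dc, shift = shift)
  dn <- delta_neighbor(D, rho)
  lam <- dp_index(rho, dn$delta)
  centers <- select_centers(lam, K, rho)
  L <- assign_labels(rho, dn$n_up, centers, D)
  list(labels = L,
       state = list(D = D, dc = dc, rho = rho, delta = dn$delta,
                    n_up = dn$n_up, lam = lam, centers = centers))
}
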