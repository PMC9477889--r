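# Deterministic eigenvector sign: largest-magnitude entry of each column
# made positive, so repeated runs and different BLAS builds agree.
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' Initialize the projection by principal components
#'
#' The subspace the iteration starts from: the top `d` principal
#' directions of the column-centered waveform matrix, with a deterministic
#' sign convention.
#'
#' @param X `n x p` waveform matrix (rows = spikes).
#' @param d Subspace dimension (default 3).
#' @return `p x d` projection matrix with orthonormal columns; attribute
#'   `source = "pca"`.
#' @export
pca_init <- function(X, d = 3) {
  X <- as.matrix(X)
  if (nrow(X) <= d) stop("need more than d = ", d, " spikes")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-10 & sv$d > 0)
  if (rank < d)
    stop("centered waveform matrix has rank ", rank,
         ", cannot extract d = ", d, " components")
  W <- fix_signs(sv$v[, seq_len(d), drop = FALSE])
  attr(W, "source") <- "pca"
  W
}

#' Within- and between-class scatter matrices
#'
#' The within-class scatter `Sw` is the unnormalized sum over clusters of
#' member deviations from the cluster mean; the between-class scatter `Sb`
#' is the count-weighted outer product of cluster-mean deviations from the
#' global mean, divided by the total number of points.
#'
#' @param Y `n x p` data matrix (waveforms or features).
#' @param L Integer cluster label per row.
#' @return List with `Sw`, `Sb` (`p x p`), per-cluster `means`, global
#'   mean `mu`, `counts`, `n`.
#' @examples
#' sm <- scatter_matrices(matrix(c(0, 2, 10, 12)), c(1, 1, 2, 2))
#' c(sm$Sw, sm$Sb)  # 4, 25
#' @export
scatter_matrices <- function(Y, L) {
  Y <- as.matrix(Y)
  L <- as.integer(L)
  stopifnot(nrow(Y) == length(L))
  ids <- sort(unique(L))
  counts <- tabulate(match(L, ids))
  if (any(counts == 0)) stop("every cluster must be non-empty")
  n <- nrow(Y); p <- ncol(Y)
  mu <- colMeans(Y)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  means <- matrix(0, length(ids), p)
  for (k in seq_along(ids)) {
    Yk <- Y[L == ids[k], , drop = FALSE]
    mk <- colMeans(Yk)
    means[k, ] <- mk
    Sw <- Sw + crossprod(sweep(Yk, 2, mk))
    dm <- mk - mu
    Sb <- Sb + counts[k] * tcrossprod(dm)
  }
  Sb <- Sb / n
  list(Sw = Sw, Sb = Sb, means = means, mu = mu, counts = counts, n = n)
}

#' Discriminant trace-ratio objective
#'
#' `J(W) = tr(W' Sb W) / tr(W' Sw W)`, the criterion the supervised
#' subspace maximizes: large between-class and small within-class scatter.
#'
#' @param W `p x d` projection.
#' @param Sw,Sb Scatter matrices from [scatter_matrices()].
#' @return Scalar objective value.
#' @export
discriminant_ratio <- function(W, Sw, Sb) {
  sum(diag(crossprod(W, Sb %*% W))) / sum(diag(crossprod(W, Sw %*% W)))
}

#' Fit the supervised linear discriminant projection
#'
#' Re-estimates the projection from the current cluster labels. The
#' default solver is the standard ratio-trace relaxation: the top `d`
#' generalized eigenvectors of `(Sw + eps*I, Sb)`, computed through a
#' Cholesky whitening of the regularized `Sw`. `trace_ratio = TRUE`
#' refines this solution toward the exact trace-ratio optimum with
#' Dinkelbach iterations (solving `Sb - lambda*Sw` eigenproblems until the
#' objective is stationary).
#'
#' @param X `n x p` waveform matrix.
#' @param L Integer labels (at least two distinct clusters).
#' @param d Subspace dimension (default 3).
#' @param ridge Relative ridge added to `Sw` before inversion
#'   (`ridge * tr(Sw)/p`, default 1e-6), needed when clusters are tight or
#'   `p > n`.
#' @param trace_ratio Refine with Dinkelbach iterations (default FALSE).
#' @return `p x d` projection matrix, attribute `source = "lda"`.
#' @export
lda_fit <- function(X, L, d = 3, ridge = 1e-6, trace_ratio = FALSE) {
  X <- as.matrix(X)
  if (length(unique(L)) < 2)
    stop("LDA needs at least 2 clusters; got 1")
  p <- ncol(X)
  if (d > p) stop("d must not exceed the waveform dimension")
  sm <- scatter_matrices(X, L)
  eps <- ridge * sum(diag(sm$Sw)) / p
  if (eps <= 0) eps <- ridge
  Swr <- sm$Sw + diag(eps, p)
  R <- chol(Swr)
  Rinv <- backsolve(R, diag(p))
  A <- crossprod(Rinv, sm$Sb %*% Rinv)
  A <- (A + t(A)) / 2
  V <- eigen(A, symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
  W <- Rinv %*% V
  # orthonormal basis of the discriminant span: the trace-ratio objective
  # is posed under W'W = I and depends only on the span, and an
  # orthonormal W keeps feature-space geometry commensurate with
  # waveform space (whitened columns would inflate low-variance
  # directions, distorting the compactness/separation ratios downstream)
  W <- qr.Q(qr(W))
  if (trace_ratio) {
    lam <- discriminant_ratio(W, Swr, sm$Sb)
    for (it in 1:50) {
      M <- sm$Sb - lam * Swr
      W <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, seq_len(d),
                                                           drop = FALSE]
      lam_new <- discriminant_ratio(W, Swr, sm$Sb)
      if (abs(lam_new - lam) < 1e-12 * max(1, abs(lam))) break
      lam <- lam_new
    }
  }
  W <- fix_signs(W)
  attr(W, "source") <- "lda"
  W
}

#' Project waveforms into the feature subspace
#'
#' `Y = (X - colMeans(X)) W`: column-centering is applied for both PCA-
#' and LDA-derived projections so features are comparable across
#' iterations.
#'
#' @param X `n x p` waveform matrix.
#' @param W `p x d` projection matrix.
#' @return `n x d` feature matrix.
#' @export
project_features <- function(X, W) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W))
    stop("shape mismatch: X has ", ncol(X), " columns but W has ",
         nrow(W), " rows")
  sweep(X, 2, colMeans(X)) %*% W
}
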