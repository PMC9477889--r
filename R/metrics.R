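# All permutations of 1..n, rows of an (n!) x n matrix. Used for exact
# one-to-one label matching; n <= 8 keeps this trivial.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

# Maximum sum of matched cells of a contingency table over one-to-one
# row-to-column mappings. Exact (exhaustive) for tables up to 8 x 8;
# greedy beyond that (spike-sorting cluster counts are small).
best_label_matching <- function(tab) {
  tab <- as.matrix(tab)
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  if (k <= 8) {
    perms <- permutations_of(k)
    scores <- apply(perms, 1, function(p) sum(sq[cbind(seq_len(k), p)]))
    best <- which.max(scores)
    list(score = scores[best], mapping = perms[best, ])
  } else {
    mapping <- integer(k)
    used <- logical(k)
    ord <- order(-apply(sq, 1, max))
    for (i in ord) {
      j <- order(-sq[i, ])
      j <- j[!used[j]][1]
      mapping[i] <- j
      used[j] <- TRUE
    }
    list(score = sum(sq[cbind(seq_len(k), mapping)]), mapping = mapping)
  }
}

#' Sorting accuracy under optimal label matching
#'
#' Fraction of spikes assigned to the right unit after the best one-to-one
#' mapping between predicted and true cluster ids (predicted ids are
#' arbitrary, so a permutation must be absorbed before counting). Spikes
#' with an excluded truth id (e.g. overlap events marked 0) should be
#' filtered out by the caller beforehand.
#'
#' @param pred Predicted integer labels.
#' @param truth True integer labels, same length.
#' @return Accuracy in `[0, 1]`, with the label mapping used attached as
#'   attribute `mapping` (named by predicted id).
#' @examples
#' sorting_accuracy(c(2, 2, 1, 1), c(1, 1, 2, 2))  # 1
#' @export
sorting_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  tab <- table(factor(pred), factor(truth))
  m <- best_label_matching(tab)
  acc <- m$score / length(pred)
  attr(acc, "mapping") <- m$mapping
  acc
}

#' Davies-Bouldin index
#'
#' Cluster-validity score requiring no ground truth: for each cluster,
#' take the worst-case similarity ratio `(CP_a + CP_b)/SP_ab` against any
#' other cluster, and average. Compactness and separation here use the
#' cluster centroids (the standard DBI), unlike the merging step which
#' uses density-peaks exemplars. Lower is better.
#'
#' @param Y `n x d` feature matrix.
#' @param L Integer labels with at least 2 distinct values.
#' @return Scalar DBI.
#' @export
dbi <- function(Y, L) {
  Y <- as.matrix(Y)
  ids <- sort(unique(L))
  K <- length(ids)
  if (K < 2) stop("DBI needs at least 2 clusters")
  L <- match(L, ids)
  centroids <- matrix(vapply(seq_len(K),
                             function(k) colMeans(Y[L == k, , drop = FALSE]),
                             numeric(ncol(Y))),
                      nrow = K, byrow = TRUE)
  CP <- compactness(Y, L, centroids)
  SP <- separation(centroids)
  R <- cluster_similarity(CP, SP)
  mean(apply(R, 1, max, na.rm = TRUE))
}

#' Precision and recall against marked (partial-ground-truth) spikes
#'
#' Treats sorting of a partially ground-truthed recording as binary
#' classification of each spike as the marked unit or not. When `pred` is
#' a label vector, the predicted unit is the cluster with the largest
#' overlap (TP) with the marked set; a logical `pred` is used directly.
#' Precision = TP/(TP+FP) (one minus the false-positive rate of the
#' unit's spikes), recall = TP/(TP+FN).
#'
#' @param pred Integer cluster labels, or logical flags for one unit.
#' @param marked Logical per spike: matched to an intracellular peak.
#' @return List with `precision`, `recall`, `counts` (TP, FP, TN, FN) and
#'   `unit` (selected cluster id, or NA for logical input).
#' @export
precision_recall <- function(pred, marked) {
  marked <- as.logical(marked)
  if (length(pred) != length(marked))
    stop("pred and marked must have equal length")
  if (!any(marked)) stop("no marked spikes to evaluate against")
  if (is.logical(pred)) {
    flags <- pred
    unit <- NA_integer_
  } else {
    ids <- sort(unique(pred))
    tp_by <- vapply(ids, function(k) sum(pred == k & marked), numeric(1))
    unit <- ids[which.max(tp_by)]
    flags <- pred == unit
  }
  TP <- sum(flags & marked)
  FP <- sum(flags & !marked)
  FN <- sum(!flags & marked)
  TN <- sum(!flags & !marked)
  list(precision = TP / (TP + FP), recall = TP / (TP + FN),
       counts = c(TP = TP, FP = FP, TN = TN, FN = FN), unit = unit)
}

#' Pairwise waveform-template correlation
#'
#' Pearson correlation between every pair of templates, the standard
#' measure of waveform similarity (highly correlated templates are the
#' hard sorting cases).
#'
#' @param templates `n_templates x wave_len` matrix, or a `template_bank`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
template_correlation <- function(templates) {
  if (inherits(templates, "template_bank")) templates <- templates$templates
  templates <- as.matrix(templates)
  if (nrow(templates) < 2) stop("need at least 2 templates")
  sds <- apply(templates, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance template at row ", which(sds == 0)[1])
  cc <- stats::cor(t(templates))
  dimnames(cc) <- NULL
  cc
}
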