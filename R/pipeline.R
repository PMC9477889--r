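#' Run configuration for the sorter
#'
#' Collects and validates every tunable parameter of the pipeline with
#' the recommended defaults: 4 initial clusters, a 3-dimensional feature
#' subspace, cutoff-distance index 0.015, merge coefficient 1.6,
#' between 5 and 50 iterations, 300-3000 Hz detection band with a 4x
#' median threshold, 64-sample waveforms aligned at sample 20, and a
#' 0.3 ms ground-truth matching tolerance.
#'
#' @param K_init Initial number of clusters seeded each iteration.
#' @param d Feature-subspace dimension.
#' @param t Cutoff-distance index; warned outside `[0.01, 0.02]`.
#' @param alpha Merge-threshold coefficient (> 1; recommended above 1.4).
#' @param min_ite,max_ite Iteration bounds.
#' @param convergence Label-agreement fraction declaring convergence.
#' @param band Detection passband (Hz).
#' @param thresh_mult Detection threshold multiplier.
#' @param wave_len Samples per waveform.
#' @param peak_index 1-based alignment sample of the peak.
#' @param match_tol_ms Ground-truth matching tolerance (ms).
#' @param squared,shift,rank_basis Density-peaks conventions, see
#'   [dp_cluster()].
#' @param use_centroid,rth_denominator Merging conventions, see
#'   [merge_clusters()].
#' @param trace_ratio Refine the discriminant solver, see [lda_fit()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(K_init = 4, d = 3, t = 0.015, alpha = 1.6,
                       min_ite = 5, max_ite = 50, convergence = 0.99,
                       band = c(300, 3000), thresh_mult = 4,
                       wave_len = 64, peak_index = 20, match_tol_ms = 0.3,
                       squared = TRUE, shift = TRUE, rank_basis = "pairs",
                       use_centroid = FALSE, rth_denominator = "pairs",
                       trace_ratio = FALSE) {
  if (!(t > 0 && t < 1)) stop("t must lie in (0, 1)")
  if (t < 0.01 || t > 0.02)
    warning("t = ", t, " is outside the usual 0.01-0.02 range")
  if (alpha <= 1) stop("alpha must exceed 1")
  if (min_ite > max_ite) stop("min_ite must not exceed max_ite")
  if (peak_index < 1 || peak_index > wave_len)
    stop("peak_index must lie in [1, wave_len]")
  if (d < 1 || K_init < 2) stop("need d >= 1 and K_init >= 2")
  structure(list(K_init = K_init, d = d, t = t, alpha = alpha,
                 min_ite = min_ite, max_ite = max_ite,
                 convergence = convergence, band = band,
                 thresh_mult = thresh_mult, wave_len = wave_len,
                 peak_index = peak_index, match_tol_ms = match_tol_ms,
                 squared = squared, shift = shift, rank_basis = rank_basis,
                 use_centroid = use_centroid,
                 rth_denominator = rth_denominator,
                 trace_ratio = trace_ratio),
            class = "run_config")
}

#' Label agreement between two clusterings
#'
#' Maximum fraction of identically-assigned points over all one-to-one
#' matchings of cluster ids (cluster numbering is arbitrary between
#' iterations, so a permutation of ids counts as full agreement). This is
#' the pipeline's convergence measure.
#'
#' @param L,L_pre Equal-length integer label vectors.
#' @return Fraction in `[0, 1]`.
#' @examples
#' label_agreement(c(1, 1, 2), c(2, 2, 1))  # 1
#' @export
label_agreement <- function(L, L_pre) {
  if (length(L) != length(L_pre)) stop("label vectors must have equal length")
  as.numeric(sorting_accuracy(L, L_pre))
}

#' Sort spikes by joint discriminant-subspace / density-peaks iteration
#'
#' The full sorter. The projection is initialized by PCA; each iteration
#' projects the waveforms, clusters the features with density peaks
#' (always seeding `K_init` clusters), and — unless converged — refits
#' the discriminant projection from the fresh labels. Convergence is
#' declared once at least `min_ite` iterations have run and the labels
#' agree with the previous iteration's at the `convergence` fraction
#' (under optimal id matching); the loop always stops at `max_ite`. The
#' final clusters are then merged wherever their compactness/separation
#' similarity exceeds the adaptive threshold, which fixes the number of
#' units automatically. The whole procedure is deterministic: repeated
#' calls on the same input give identical results.
#'
#' @param X `n x p` waveform matrix (rows = aligned spikes), or a
#'   `spike_waveforms` object.
#' @param config A [run_config()].
#' @param refine_subspace Re-fit the discriminant projection each
#'   iteration (default). `FALSE` keeps the PCA projection throughout —
#'   the PCA-DP ablation used as a baseline.
#' @return Object of class `sort_result`: `labels` (merged, `1..K`),
#'   `pre_merge_labels`, `n_clusters`, `iterations`, `converged`,
#'   `agreement_trace` (per iteration; `NA` for the first), `W`,
#'   `features` (final projected `Y`), `dp_state`, `merge_report`,
#'   `config`.
#' @examples
#' bank <- make_templates(3, "low", seed = 1)
#' ws <- generate_waveform_set(bank, 60, noise_level = 0.05, seed = 2)
#' res <- lda_dp_sort(ws$waves)
#' res$n_clusters
#' @export
lda_dp_sort <- function(X, config = run_config(), refine_subspace = TRUE) {
  if (inherits(X, "spike_waveforms")) X <- X$waves
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("waveform matrix contains non-finite values")
  if (nrow(X) <= config$K_init)
    stop("need more than K_init = ", config$K_init, " spikes")
  if (ncol(X) < config$d) stop("waveform length must be at least d")

  W <- pca_init(X, config$d)
  L_pre <- NULL
  agreement_trace <- numeric(0)
  converged <- FALSE
  Y <- NULL; dp <- NULL; L <- NULL
  it <- 0L
  while (it < config$max_ite) {
    it <- it + 1L
    Y <- project_features(X, W)
    dp <- dp_cluster(Y, t = config$t, K = config$K_init,
                     squared = config$squared, shift = config$shift,
                     rank_basis = config$rank_basis)
    L <- dp$labels
    ag <- if (is.null(L_pre)) NA_real_ else label_agreement(L, L_pre)
    agreement_trace[it] <- ag
    if (it >= config$min_ite && !is.na(ag) && ag >= config$convergence) {
      converged <- TRUE
      break
    }
    if (refine_subspace)
      W <- lda_fit(X, L, config$d, trace_ratio = config$trace_ratio)
    L_pre <- L
  }

  merged <- merge_clusters(Y, L, dp$state$centers, alpha = config$alpha,
                           use_centroid = config$use_centroid,
                           denominator = config$rth_denominator)
  structure(list(labels = merged$labels,
                 pre_merge_labels = L,
                 n_clusters = max(merged$labels),
                 iterations = it,
                 converged = converged,
                 agreement_trace = agreement_trace,
                 W = W,
                 features = Y,
                 dp_state = dp$state,
                 merge_report = merged$report,
                 config = config),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("sort_result: %d spikes -> %d units (%d before merging)\n",
              length(x$labels), x$n_clusters, max(x$pre_merge_labels)))
  cat(sprintf("iterations: %d (%s); final label agreement: %s\n",
              x$iterations,
              if (x$converged) "converged" else "hit max_ite",
              {
                ag <- x$agreement_trace[x$iterations]
                if (is.na(ag)) "NA" else sprintf("%.4f", ag)
              }))
  cat("unit sizes:", paste(tabulate(x$labels), collapse = ", "), "\n")
  invisible(x)
}
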