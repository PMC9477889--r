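#' Build a bank of spike waveform templates with controlled similarity
#'
#' Templates model what one electrode sees from different neurons: a
#' common biphasic spike shape (Gaussian depolarization lobe at
#' `peak_index` plus a repolarization trough) carrying per-neuron
#' deviations of comparable size. The deviations live in a 2-D plane of
#' orthonormalized perturbation shapes and are placed at equal angles, so
#' the templates are roughly equidistant from one another — the balanced
#' geometry of the standard simulated benchmarks. The deviation radius is
#' bisected until the mean pairwise Pearson correlation hits a target
#' drawn inside the requested regime: below 0.7 for `"low"` similarity,
#' in (0.85, 0.98) for `"high"` (distinct shapes, not near-copies). Every
#' template is normalized to maximum exactly 1 at column `peak_index`.
#' The search is bounded and deterministic given `seed`.
#'
#' @param n_templates Number of templates (>= 2).
#' @param similarity `"low"` or `"high"` waveform similarity regime.
#' @param wave_len Samples per waveform (default 64, about 2.5 ms at 24 kHz).
#' @param peak_index 1-based sample at which the peak is aligned (default 20).
#' @param seed Integer seed making the bank reproducible.
#' @param max_tries Bounded search budget before giving up.
#' @return An object of class `template_bank`: a list with `templates`
#'   (`n_templates x wave_len` matrix), `cc_matrix` (realized pairwise
#'   correlations), `wave_len` and `peak_index`.
#' @examples
#' bank <- make_templates(3, "low", seed = 1)
#' range(bank$cc_matrix[upper.tri(bank$cc_matrix)])
#' @export
make_templates <- function(n_templates = 3,
                           similarity = c("low", "high"),
                           wave_len = 64, peak_index = 20,
                           seed = NULL, max_tries = 2000) {
  similarity <- match.arg(similarity)
  if (n_templates < 2) stop("n_templates must be >= 2")
  if (peak_index < 1 || peak_index > wave_len)
    stop("peak_index must lie in [1, wave_len]")
  if (!is.null(seed)) set.seed(seed)
  s <- seq_len(wave_len)
  g <- function(center, width) exp(-(s - center)^2 / (2 * width^2))

  build <- function(radius, base, U1, U2, theta0) {
    th <- theta0 + 2 * pi * (seq_len(n_templates) - 1) / n_templates
    t(vapply(th, function(a) {
      v <- base + radius * sqrt(sum(base^2)) * (cos(a) * U1 + sin(a) * U2)
      v <- v - mean(v)   # AC-coupled: extracellular waveforms carry no DC
      v / max(v)
    }, numeric(wave_len)))
  }
  mean_cc <- function(tm) mean(stats::cor(t(tm))[upper.tri(diag(nrow(tm)))])
  ok_bank <- function(tm) {
    if (any(apply(tm, 1, function(v) which.max(abs(v))) != peak_index))
      return(FALSE)
    # peak-dominant shapes: a trough or secondary bump rivalling the
    # peak would make noisy peak alignment bimodal (shifted copies of a
    # unit would masquerade as extra clusters)
    near <- abs(seq_len(wave_len) - peak_index) <= 2
    if (any(abs(tm[, !near, drop = FALSE]) > 0.85)) return(FALSE)
    # troughs well below the peak: under noise, alignment must not flip
    # between the peak and the trough
    if (min(tm) < -0.7) return(FALSE)
    off <- stats::cor(t(tm))[upper.tri(diag(nrow(tm)))]
    if (similarity == "low") all(off < 0.7) else all(off > 0.85 & off < 0.98)
  }

  for (i in seq_len(max_tries)) {
    target <- if (similarity == "low") stats::runif(1, 0.4, 0.65)
              else stats::runif(1, 0.86, 0.92)
    base <- g(peak_index, stats::runif(1, 2, 3.5)) -
      stats::runif(1, 0.25, 0.45) *
        g(peak_index + stats::runif(1, 8, 12), stats::runif(1, 4, 7))
    # deviations are sharper than the background shapes: neurons seen by
    # one electrode differ mostly in fine temporal detail, while the
    # summed background is comparatively smooth
    # deviation widths stay sharp but inside the 300-3000 Hz band at the
    # default 24 kHz sampling (width >= ~1.3 samples)
    d1 <- g(peak_index + stats::runif(1, 5, 10), stats::runif(1, 1.3, 2.2)) -
      stats::runif(1, 0.2, 0.5) *
        g(peak_index + stats::runif(1, 14, 22), stats::runif(1, 2, 5))
    d2 <- g(peak_index - stats::runif(1, 4, 8), stats::runif(1, 1.3, 2.2)) -
      stats::runif(1, 0.2, 0.5) *
        g(peak_index + stats::runif(1, 8, 16), stats::runif(1, 2, 5))
    # deviations vanish near the peak so the unit-peak normalization is
    # the same for every template and the equal-angle construction keeps
    # the pairwise template distances balanced
    mask <- 1 - g(peak_index, 2.5)
    d1 <- d1 * mask
    d2 <- d2 * mask
    # orthonormalize the deviation plane against the base shape
    U1 <- d1 - base * sum(d1 * base) / sum(base^2)
    U1 <- U1 / sqrt(sum(U1^2))
    U2 <- d2 - base * sum(d2 * base) / sum(base^2) - U1 * sum(d2 * U1)
    if (sum(U2^2) < 1e-12) next
    U2 <- U2 / sqrt(sum(U2^2))
    theta0 <- stats::runif(1, 0, 2 * pi)
    # bisect the deviation radius to hit the target mean correlation
    lo <- 0.01; hi <- 4
    for (b in 1:60) {
      mid <- (lo + hi) / 2
      if (mean_cc(build(mid, base, U1, U2, theta0)) > target) lo <- mid
      else hi <- mid
    }
    tm <- build((lo + hi) / 2, base, U1, U2, theta0)
    if (ok_bank(tm)) {
      cc <- stats::cor(t(tm))
      dimnames(cc) <- NULL
      return(structure(list(templates = tm, cc_matrix = cc,
                            wave_len = wave_len, peak_index = peak_index,
                            similarity = similarity),
                       class = "template_bank"))
    }
  }
  stop("could not construct a ", similarity,
       "-similarity bank within ", max_tries, " tries")
}

#' @export
print.template_bank <- function(x, ...) {
  cc <- x$cc_matrix[upper.tri(x$cc_matrix)]
  cat(sprintf("template_bank: %d templates x %d samples (peak at %d), %s similarity\n",
              nrow(x$templates), x$wave_len, x$peak_index, x$similarity))
  cat(sprintf("pairwise waveform correlation: [%.3f, %.3f]\n",
              min(cc), max(cc)))
  invisible(x)
}

# Background noise built the classic simulated-benchmark way: a dense
# superposition of many randomly timed, randomly chosen spike shapes
# (drawn from a varied catalog, emulating the multitude of distant
# neurons), rescaled to exactly `sd_target`. The density (~6 overlapping
# shapes per sample) makes the summed amplitude distribution
# near-Gaussian while the power spectrum stays spike-like.
spike_spectrum_noise <- function(bank, n_samples, sd_target, n_catalog = 24) {
  if (sd_target == 0) return(numeric(n_samples))
  wl <- bank$wave_len
  pk <- bank$peak_index
  s <- seq_len(wl)
  g <- function(center, width) exp(-(s - center)^2 / (2 * width^2))
  catalog <- t(vapply(seq_len(n_catalog), function(k) {
    v <- g(pk + stats::runif(1, -3, 3), stats::runif(1, 1.5, 4)) -
      stats::runif(1, 0.2, 0.6) *
        g(pk + stats::runif(1, 4, 14), stats::runif(1, 3, 8))
    stats::runif(1, 0.5, 1) * v / max(abs(v))
  }, numeric(wl)))
  pool <- numeric(n_samples + 2L * wl)
  n_events <- max(50L, ceiling(length(pool) / wl * 6))
  pos <- sample.int(length(pool) - wl, n_events, replace = TRUE)
  tid <- sample.int(n_catalog, n_events, replace = TRUE)
  for (e in seq_len(n_events)) {
    idx <- pos[e]:(pos[e] + wl - 1L)
    pool[idx] <- pool[idx] + catalog[tid[e], ]
  }
  pool <- pool[(wl + 1L):(wl + n_samples)]
  pool <- pool - mean(pool)
  pool <- pool / stats::sd(pool)
  # broadband electrode/amplifier noise floor under the spike-shaped
  # background (30% of the total sd, in quadrature): real recordings are
  # never noise-free in any direction of waveform space
  white_frac <- 0.3
  out <- sqrt(1 - white_frac^2) * pool +
    white_frac * stats::rnorm(n_samples)
  out * (sd_target / stats::sd(out))
}

#' Generate a pre-cut, aligned waveform set with ground-truth labels
#'
#' The detection-free shortcut feeding the sorter directly: each row is one
#' template plus a segment of spike-spectrum-matched background noise of
#' standard deviation `noise_level` (relative to the unit template peak).
#' Rows are extracted at the known (ground-truth) spike times, so each
#' template's peak sits exactly at column `peak_index`; detection-based
#' alignment jitter is deliberately absent from this path (use
#' [generate_recording()] plus [detect_and_align()] to include it).
#'
#' @param bank A [make_templates()] bank.
#' @param n_per_cluster Spikes per template.
#' @param noise_level Noise standard deviation relative to template peak (=1).
#' @param seed Integer seed.
#' @return A list with `waves` (`n_templates*n_per_cluster x wave_len`
#'   matrix), `labels` (true template id per row), `noise_level`,
#'   `peak_index`.
#' @examples
#' bank <- make_templates(3, "low", seed = 1)
#' ws <- generate_waveform_set(bank, 50, noise_level = 0.05, seed = 2)
#' dim(ws$waves)
#' @export
generate_waveform_set <- function(bank, n_per_cluster, noise_level, seed = NULL) {
  stopifnot(inherits(bank, "template_bank"), n_per_cluster >= 1,
            noise_level >= 0)
  if (!is.null(seed)) set.seed(seed)
  wl <- bank$wave_len
  pk <- bank$peak_index
  margin <- min(8L, wl - pk, pk - 1L)
  seg_len <- wl + 2L * margin
  n_t <- nrow(bank$templates)
  n <- n_t * n_per_cluster
  labels <- rep(seq_len(n_t), each = n_per_cluster)

  pool <- spike_spectrum_noise(bank, n * seg_len + seg_len, noise_level)
  waves <- matrix(0, n, wl)
  for (i in seq_len(n)) {
    off <- (i - 1L) * seg_len
    seg <- pool[(off + 1L):(off + seg_len)]
    seg[(margin + 1L):(margin + wl)] <-
      seg[(margin + 1L):(margin + wl)] + bank$templates[labels[i], ]
    # cut at the known insertion point: waveforms are extracted at the
    # ground-truth spike times, so every row carries its template peak
    # exactly at peak_index (re-detecting the peak under noise would add
    # alignment jitter the benchmark's known-time extraction avoids)
    waves[i, ] <- seg[(margin + 1L):(margin + wl)]
  }
  list(waves = waves, labels = labels, noise_level = noise_level,
       peak_index = pk)
}

#' Simulate a continuous extracellular recording with ground truth
#'
#' Each unit fires as a Poisson process at its requested rate with a 2 ms
#' refractory deletion; its template is added to the trace at every event.
#' Background noise is a dense superposition of low-amplitude spike shapes
#' rescaled to `noise_level`, so its power spectrum matches the spikes.
#' Ground-truth peak times and unit labels are recorded before any overlap.
#'
#' @param bank A [make_templates()] bank.
#' @param rates Firing rate in Hz, recycled over units.
#' @param duration Recording length in seconds (>= 1).
#' @param noise_level Background noise sd relative to template peak.
#' @param fs Sampling rate in Hz (default 24000).
#' @param seed Integer seed.
#' @param refractory_ms Minimum interspike interval per unit (default 2 ms).
#' @return An object of class `recording_bundle`: list with `trace`, `fs`,
#'   `gt_times` (1-based peak sample indices, sorted), `gt_labels`,
#'   `noise_level`.
#' @export
generate_recording <- function(bank, rates = 5, duration = 10,
                               noise_level = 0.1, fs = 24000,
                               seed = NULL, refractory_ms = 2) {
  stopifnot(inherits(bank, "template_bank"), duration >= 1, all(rates > 0))
  if (!is.null(seed)) set.seed(seed)
  n_t <- nrow(bank$templates)
  rates <- rep_len(rates, n_t)
  wl <- bank$wave_len
  pk <- bank$peak_index
  n_samples <- round(duration * fs)
  refr <- refractory_ms / 1000

  times <- integer(0); labels <- integer(0)
  for (k in seq_len(n_t)) {
    # oversample the Poisson train, then refractory deletion
    isi <- stats::rexp(ceiling(rates[k] * duration * 2) + 20, rate = rates[k])
    tt <- cumsum(isi)
    tt <- tt[tt < duration - (wl / fs)]
    n_raw <- length(tt)
    keep <- logical(n_raw)
    last <- -Inf
    for (e in seq_len(n_raw)) {
      if (tt[e] - last >= refr) { keep[e] <- TRUE; last <- tt[e] }
    }
    if (n_raw > 0 && sum(!keep) / n_raw > 0.5)
      warning("refractory deletion removed more than half of unit ", k,
              "'s events; rate ", rates[k], " Hz is too high")
    st <- pmax(round(tt[keep] * fs) + 1L, pk)
    times <- c(times, as.integer(st))
    labels <- c(labels, rep(k, length(st)))
  }
  ord <- order(times)
  times <- times[ord]; labels <- labels[ord]

  trace <- spike_spectrum_noise(bank, n_samples, noise_level)
  for (e in seq_along(times)) {
    idx <- (times[e] - pk + 1L):(times[e] - pk + wl)
    ok <- idx >= 1L & idx <= n_samples
    trace[idx[ok]] <- trace[idx[ok]] + bank$templates[labels[e], ok]
  }
  structure(list(trace = trace, fs = fs, gt_times = times,
                 gt_labels = labels, noise_level = noise_level),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("recording_bundle: %.2f s at %g Hz (%d samples)\n",
              length(x$trace) / x$fs, x$fs, length(x$trace)))
  if (!is.null(x$gt_times))
    cat(sprintf("ground truth: %d spikes, %d units\n", length(x$gt_times),
                length(unique(x$gt_labels))))
  invisible(x)
}
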