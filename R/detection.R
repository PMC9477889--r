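#' Zero-phase Butterworth band-pass filter
#'
#' Filters a raw extracellular trace into the spike band with a 4th-order
#' Butterworth filter applied forward and backward (zero phase), the
#' standard preprocessing before threshold detection.
#'
#' @param trace Numeric voltage samples.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 passband in Hz, default `c(300, 3000)`.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered trace, same length as the input.
#' @export
bandpass_filter <- function(trace, fs, band = c(300, 3000), order = 4) {
  stopifnot(is.numeric(trace), length(band) == 2)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("passband must satisfy 0 < low < high < fs/2 (Nyquist)")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # reflect-pad so the forward-backward transients die out off-trace
  n <- length(trace)
  np <- min(n - 1L, as.integer(ceiling(0.25 * fs)))
  padded <- c(2 * trace[1] - trace[(np + 1L):2L], trace,
              2 * trace[n] - trace[(n - 1L):(n - np)])
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[(np + 1L):(np + n)]
}

#' Median-based spike detection threshold
#'
#' The robust amplitude threshold `Vth = mult * median(|x|) / 0.6745`,
#' applied at both polarities. The constant 0.6745 is the median of the
#' absolute value of a standard normal, so `median(|x|)/0.6745` estimates
#' the noise standard deviation without being inflated by the spikes.
#'
#' @param filtered Band-passed trace.
#' @param mult Threshold multiplier (default 4).
#' @return Positive threshold magnitude.
#' @examples
#' detection_threshold(rep(c(0.6745, -0.6745), 50))  # 4
#' @export
detection_threshold <- function(filtered, mult = 4) {
  if (length(filtered) == 0) stop("empty trace")
  vth <- mult * stats::median(abs(filtered)) / 0.6745
  if (vth == 0) warning("degenerate trace: detection threshold is 0")
  vth
}

#' Detect spikes and cut aligned waveforms
#'
#' Finds excursions of the filtered trace beyond +/-`Vth` (double, i.e.
#' either-polarity thresholding), takes the sample of maximal `|x|` within
#' each excursion as the spike peak, suppresses peaks falling within the
#' refractory window of a larger peak, drops events too close to the trace
#' edges, and cuts `wave_len`-sample windows with the peak at `peak_index`.
#'
#' @param filtered Band-passed trace.
#' @param fs Sampling rate in Hz.
#' @param threshold Threshold magnitude; computed from
#'   [detection_threshold()] with `mult` when `NULL`.
#' @param mult Threshold multiplier used when `threshold` is `NULL`.
#' @param wave_len Samples per cut waveform (default 64).
#' @param peak_index 1-based alignment column for the peak (default 20).
#' @param refractory_ms Suppression window in ms (default 1).
#' @return An object of class `spike_waveforms`: list with `waves`
#'   (`n x wave_len`), `times` (peak sample index per spike, increasing),
#'   `fs`, `peak_index`, `threshold`. `n = 0` is allowed.
#' @export
detect_and_align <- function(filtered, fs, threshold = NULL, mult = 4,
                             wave_len = 64, peak_index = 20,
                             refractory_ms = 1) {
  stopifnot(peak_index >= 1, peak_index <= wave_len)
  vth <- if (is.null(threshold)) detection_threshold(filtered, mult) else threshold
  n <- length(filtered)
  ax <- abs(filtered)
  above <- ax > vth
  peaks <- integer(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    peaks <- vapply(runs, function(k) {
      s <- starts[k]
      s - 1L + which.max(ax[s:ends[k]])
    }, integer(1))
  }
  # refractory suppression: keep larger peaks, drop smaller ones nearby
  refr <- round(refractory_ms / 1000 * fs)
  if (length(peaks) > 1 && refr > 0) {
    ord <- order(-ax[peaks], peaks)
    kept <- integer(0)
    for (p in peaks[ord]) {
      if (!length(kept) || all(abs(kept - p) >= refr)) kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  # alignment: re-center each window on its absolute maximum so every
  # cut row peaks exactly at peak_index; windows that slide onto the
  # same dominant peak collapse to one event (sub-window overlaps are
  # not resolved — the smaller spike is absorbed)
  aligned <- integer(0)
  for (p in peaks) {
    for (pass in 1:5) {
      lo <- p - peak_index + 1L
      hi <- p + wave_len - peak_index
      if (lo < 1L || hi > n) { p <- NA_integer_; break }
      m <- lo - 1L + which.max(ax[lo:hi])
      if (m == p) break
      p <- m
    }
    if (!is.na(p)) aligned <- c(aligned, p)
  }
  peaks <- sort(unique(aligned))
  waves <- matrix(0, length(peaks), wave_len)
  for (i in seq_along(peaks)) {
    waves[i, ] <- filtered[(peaks[i] - peak_index + 1L):
                           (peaks[i] + wave_len - peak_index)]
  }
  structure(list(waves = waves, times = peaks, fs = fs,
                 peak_index = peak_index, threshold = vth),
            class = "spike_waveforms")
}

#' @export
print.spike_waveforms <- function(x, ...) {
  cat(sprintf("spike_waveforms: %d spikes x %d samples (peak at %d), fs = %g Hz\n",
              nrow(x$waves), ncol(x$waves), x$peak_index, x$fs))
  invisible(x)
}

#' Match extracellular spikes to intracellular ground-truth peaks
#'
#' One-to-one matching of detected extracellular spike times against
#' intracellular action-potential peak times: candidate pairs within
#' `tol_ms` are accepted greedily in order of increasing time difference,
#' so each intracellular peak claims its nearest available extracellular
#' spike. Matched extracellular spikes are the "marked" spikes used as
#' partial ground truth.
#'
#' @param extra_times Extracellular spike times (sample indices, sorted).
#' @param intra_times Intracellular peak times (sample indices, sorted).
#' @param fs Sampling rate in Hz.
#' @param tol_ms Matching tolerance in ms (default 0.3).
#' @return List with `marked` (logical per extracellular spike) and
#'   `pairs` (matrix with columns `intra`, `extra`, `dt_samples`).
#' @export
match_ground_truth <- function(extra_times, intra_times, fs, tol_ms = 0.3) {
  tol <- tol_ms / 1000 * fs
  ne <- length(extra_times); ni <- length(intra_times)
  marked <- logical(ne)
  pairs <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("intra", "extra", "dt_samples")))
  if (ne == 0 || ni == 0) return(list(marked = marked, pairs = pairs))
  cand <- do.call(rbind, lapply(seq_len(ni), function(i) {
    dt <- abs(extra_times - intra_times[i])
    j <- which(dt <= tol)
    if (!length(j)) return(NULL)
    cbind(i, j, dt[j])
  }))
  if (is.null(cand)) return(list(marked = marked, pairs = pairs))
  cand <- cand[order(cand[, 3], cand[, 1]), , drop = FALSE]
  used_i <- logical(ni); used_e <- logical(ne)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_i[i] && !used_e[j]) {
      used_i[i] <- TRUE; used_e[j] <- TRUE; keep[r] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  colnames(pairs) <- c("intra", "extra", "dt_samples")
  marked[pairs[, "extra"]] <- TRUE
  list(marked = marked, pairs = pairs)
}
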