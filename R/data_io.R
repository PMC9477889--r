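#' Read a delimited spike-waveform matrix
#'
#' Reads a rectangular numeric table (one spike per row) from CSV, TSV or
#' whitespace-delimited text; the delimiter is auto-detected. The
#' waveform length is taken from the column count.
#'
#' @param path File path.
#' @return Numeric `n_spikes x wave_len` matrix.
#' @export
read_waveform_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no spikes: ", path, " is empty")
  sep <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else ""
  fields <- if (sep == "") strsplit(trimws(lines), "[[:space:]]+")
            else strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(fields)
  if (length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    stop("ragged table: row ", bad, " has ", lens[bad],
         " fields, expected ", lens[1])
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) stop("non-numeric entries in ", path)
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

#' Write a spike-waveform matrix as delimited text
#'
#' @param waves Numeric matrix or `spike_waveforms` object.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_waveform_matrix <- function(waves, path, sep = ",") {
  if (inherits(waves, "spike_waveforms")) waves <- waves$waves
  data.table::fwrite(data.table::as.data.table(waves), path, sep = sep,
                     col.names = FALSE)
  invisible(path)
}

#' Write a sort result to a JSON file
#'
#' Serializes the labels, pre-merge labels, cluster count, iteration
#' trace, projection matrix, merge history and the configuration echo.
#' [read_sort_result()] inverts it (the density-peaks state and feature
#' matrix are not serialized).
#'
#' @param result A `sort_result` from [lda_dp_sort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sort_result <- function(result, path) {
  stopifnot(inherits(result, "sort_result"))
  payload <- list(
    n_clusters = result$n_clusters,
    labels = result$labels,
    pre_merge_labels = result$pre_merge_labels,
    iterations = result$iterations,
    converged = result$converged,
    agreement_trace = result$agreement_trace,
    W = result$W,
    merge_report = list(
      final_K = result$merge_report$final_K,
      merges = result$merge_report$merges,
      Rth_history = result$merge_report$Rth_history,
      R_history = result$merge_report$R_history
    ),
    config = unclass(result$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a sort result written by [write_sort_result()]
#'
#' @param path JSON file path.
#' @return A `sort_result`-classed list (without `dp_state`/`features`).
#' @export
read_sort_result <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  x$labels <- as.integer(x$labels)
  x$pre_merge_labels <- as.integer(x$pre_merge_labels)
  x$agreement_trace <- as.numeric(x$agreement_trace)
  x$merge_report$merges <- as.data.frame(x$merge_report$merges)
  x$config <- do.call(run_config, x$config[names(x$config) %in%
                                             names(formals(run_config))])
  structure(x, class = "sort_result")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(run_config, x[names(x) %in% names(formals(run_config))])
}

#' Read a wave_clus-style simulated recording
#'
#' Loads a MAT-file with the benchmark layout: a continuous trace in
#' `data`, optional ground-truth spike times in `spike_times` and classes
#' in `spike_class` (class 0 marks overlap events and is preserved; the
#' evaluation harness excludes those spikes). Different releases store
#' spike times in milliseconds or samples; `time_units` selects the
#' convention (default `"samples"`) and the assumption is logged with a
#' message. Only the MAT v5 dialect is supported.
#'
#' @param path MAT-file path.
#' @param fs Sampling rate override (Hz); when `NULL`, taken from an `sr`
#'   field if present, else 24000 with a message.
#' @param time_units `"samples"` or `"ms"` for `spike_times`.
#' @return A `recording_bundle` (see [generate_recording()]).
#' @export
read_waveclus_dataset <- function(path, fs = NULL,
                                  time_units = c("samples", "ms")) {
  time_units <- match.arg(time_units)
  vars <- read_mat5(path)
  if (is.null(vars$data))
    stop("format error: MAT-file has no 'data' field (found: ",
         paste(names(vars), collapse = ", "), ")")
  trace <- as.numeric(vars$data)
  if (is.null(fs)) {
    if (!is.null(vars$sr)) {
      fs <- as.numeric(vars$sr)[1]
    } else {
      fs <- 24000
      message("no sampling rate in file; assuming fs = 24000 Hz")
    }
  }
  if (fs <= 0) stop("sampling rate must be positive")
  gt_times <- gt_labels <- NULL
  if (!is.null(vars$spike_times)) {
    gt_times <- as.numeric(vars$spike_times)
    if (time_units == "ms") {
      message("interpreting spike_times as milliseconds")
      gt_times <- round(gt_times / 1000 * fs)
    } else {
      message("interpreting spike_times as sample indices")
    }
    gt_times <- as.integer(gt_times)
    if (!is.null(vars$spike_class)) {
      gt_labels <- as.integer(as.numeric(vars$spike_class))
      if (length(gt_labels) != length(gt_times))
        stop("consistency error: ", length(gt_times), " spike_times but ",
             length(gt_labels), " spike_class entries")
    }
    ord <- order(gt_times)
    gt_times <- gt_times[ord]
    if (!is.null(gt_labels)) gt_labels <- gt_labels[ord]
  }
  structure(list(trace = trace, fs = fs, gt_times = gt_times,
                 gt_labels = gt_labels),
            class = "recording_bundle")
}

#' Write a recording bundle as a wave_clus-style MAT v5 file
#'
#' @param bundle A `recording_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveclus_dataset <- function(bundle, path) {
  stopifnot(inherits(bundle, "recording_bundle"))
  vars <- list(data = matrix(bundle$trace, nrow = 1),
               sr = matrix(bundle$fs, 1, 1))
  if (!is.null(bundle$gt_times))
    vars$spike_times <- matrix(as.numeric(bundle$gt_times), nrow = 1)
  if (!is.null(bundle$gt_labels))
    vars$spike_class <- matrix(as.numeric(bundle$gt_labels), nrow = 1)
  write_mat5(vars, path)
  invisible(path)
}
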