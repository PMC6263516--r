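#' Construct a sensor stream
#'
#' A `sensor_stream` holds one device/sensor's uniformly or non-uniformly
#' sampled triaxial time series: a vector of strictly increasing timestamps
#' (seconds) and an N x 3 matrix of x, y, z values in device units
#' (e.g. m/s^2 for an accelerometer).
#'
#' @param device_id Device label, e.g. `"phone"` or `"watch"`.
#' @param sensor_kind `"accelerometer"` or `"gyroscope"`.
#' @param timestamps Numeric vector of strictly increasing times in seconds.
#' @param values N x 3 numeric matrix; columns are the x, y, z axes.
#' @param sampling_rate_hz Nominal sampling rate in Hz. If `NULL`, estimated
#'   as the reciprocal of the median timestamp increment.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(device_id, sensor_kind = c("accelerometer", "gyroscope"),
                          timestamps, values, sampling_rate_hz = NULL) {
  sensor_kind <- match.arg(sensor_kind)
  timestamps <- as.numeric(timestamps)
  values <- as.matrix(values)
  if (ncol(values) != 3L)
    stop("'values' must have exactly 3 columns (x, y, z)")
  if (nrow(values) != length(timestamps))
    stop("row count of 'values' must equal the number of timestamps")
  if (length(timestamps) >= 2L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(sampling_rate_hz)) {
    if (length(timestamps) < 2L)
      stop("cannot estimate sampling rate from fewer than 2 samples")
    sampling_rate_hz <- 1 / stats::median(diff(timestamps))
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  colnames(values) <- c("x", "y", "z")
  structure(
    list(device_id = as.character(device_id), sensor_kind = sensor_kind,
         sampling_rate_hz = sampling_rate_hz, timestamps = timestamps,
         values = values),
    class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s/%s: %d samples @ %.6g Hz, t = [%.3f, %.3f] s\n",
              x$device_id, x$sensor_kind, length(x$timestamps),
              x$sampling_rate_hz,
              if (length(x$timestamps)) min(x$timestamps) else NA,
              if (length(x$timestamps)) max(x$timestamps) else NA))
  invisible(x)
}

#' Load a multi-stream inertial recording from delimited text
#'
#' Reads a delimited file with one row per sample (a shared timestamp column
#' plus three value columns per declared stream) and returns one
#' [sensor_stream()] per declared stream. Rows in which the timestamp or any
#' declared value column fails to parse as a number are dropped; the count of
#' dropped rows is attached as attribute `"dropped_rows"`.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param schema A list describing the columns: `time_col` (name of the
#'   timestamp column) and `streams`, a list whose elements each have
#'   `device_id`, `sensor_kind`, and `cols` (the three axis column names, in
#'   x, y, z order).
#' @param sep Field separator (default `","`).
#' @return A list of `sensor_stream` objects, in declared stream order, with
#'   attribute `dropped_rows`.
#' @export
load_recording <- function(path, schema, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty recording file: ", path)
  needed <- c(schema$time_col, unlist(lapply(schema$streams, `[[`, "cols")))
  missing_cols <- setdiff(needed, colnames(raw))
  if (length(missing_cols))
    stop("schema error: declared column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))
  num <- suppressWarnings(
    vapply(raw[needed], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, needed))
  ok <- stats::complete.cases(num)
  dropped <- sum(!ok)
  num <- num[ok, , drop = FALSE]
  if (nrow(num) == 0L) stop("no parseable rows in recording file: ", path)
  tvec <- num[, schema$time_col]
  streams <- lapply(schema$streams, function(s) {
    sensor_stream(device_id = s$device_id,
                  sensor_kind = if (is.null(s$sensor_kind)) "accelerometer" else s$sensor_kind,
                  timestamps = tvec,
                  values = num[, s$cols, drop = FALSE])
  })
  attr(streams, "dropped_rows") <- dropped
  streams
}

#' Synchronize sensor streams onto a common uniform time grid
#'
#' Devices record on their own (possibly different-rate) clocks; before
#' windowing, all streams are resampled by linear interpolation onto a single
#' uniform grid at `target_rate_hz` spanning the intersection of their time
#' spans. Timestamps are assumed to already share a common clock.
#'
#' @param streams List of [sensor_stream()] objects.
#' @param target_rate_hz Target sampling rate of the shared grid, in Hz.
#' @return List of `sensor_stream` objects on identical timestamps.
#' @export
synchronize <- function(streams, target_rate_hz) {
  if (target_rate_hz <= 0) stop("target_rate_hz must be positive")
  if (!length(streams)) stop("no streams to synchronize")
  t0 <- max(vapply(streams, function(s) s$timestamps[1L], 0))
  t1 <- min(vapply(streams, function(s) s$timestamps[length(s$timestamps)], 0))
  if (t1 <= t0)
    stop("synchronization error: streams have no overlapping time span")
  n <- floor((t1 - t0) * target_rate_hz) + 1L
  grid <- t0 + (seq_len(n) - 1L) / target_rate_hz
  lapply(streams, function(s) {
    v <- vapply(1:3, function(j)
      stats::approx(s$timestamps, s$values[, j], xout = grid)$y,
      numeric(n))
    sensor_stream(s$device_id, s$sensor_kind, grid,
                  matrix(v, ncol = 3L), sampling_rate_hz = target_rate_hz)
  })
}

#' Construct a signal window
#'
#' A `signal_window` is the unit of classification: an N x C matrix of
#' synchronized samples (N time points, C axis columns across all streams,
#' 3 per stream) together with its activity label, subject id, start time
#' and sampling rate.
#'
#' @param samples N x C numeric matrix.
#' @param axis_labels Data frame with columns `device_id` and `axis`, one row
#'   per column of `samples`.
#' @param label Activity class label.
#' @param subject_id Subject identifier.
#' @param window_start_s Window start time in seconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return An object of class `signal_window`.
#' @export
signal_window <- function(samples, axis_labels, label, subject_id,
                          window_start_s, sampling_rate_hz) {
  samples <- as.matrix(samples)
  if (nrow(axis_labels) != ncol(samples))
    stop("axis_labels must have one row per sample column")
  if (ncol(samples) %% 3L != 0L)
    stop("sample columns must come in x/y/z triples (C divisible by 3)")
  structure(
    list(samples = samples, axis_labels = axis_labels,
         label = as.character(label), subject_id = as.character(subject_id),
         window_start_s = window_start_s, sampling_rate_hz = sampling_rate_hz),
    class = "signal_window")
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf("<signal_window> %d x %d, label=%s, subject=%s, start=%.3f s @ %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$label, x$subject_id,
              x$window_start_s, x$sampling_rate_hz))
  invisible(x)
}

#' Cut synchronized streams into labeled fixed-length windows
#'
#' Slides a fixed-width window of `window_s` seconds over the synchronized
#' streams with stride `window_s - overlap_s`. A window is emitted only when
#' it lies entirely inside a single labeled interval; windows straddling a
#' label boundary are discarded. Label intervals are half-open
#' `[start, end)`. Sample columns follow the declared stream order, axes
#' x, y, z within each stream.
#'
#' @param streams List of synchronized [sensor_stream()] objects (identical
#'   timestamps).
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between successive windows in seconds; must be
#'   strictly smaller than `window_s`.
#' @param labels Data frame of labeled intervals with columns `start`, `end`
#'   (seconds) and `label`.
#' @param subject_id Subject identifier copied onto every window.
#' @return List of [signal_window()] objects.
#' @export
segment_windows <- function(streams, window_s, overlap_s, labels,
                            subject_id = "S1") {
  if (overlap_s >= window_s)
    stop("configuration error: overlap_s must be smaller than window_s")
  if (overlap_s < 0) stop("configuration error: overlap_s must be nonnegative")
  ts0 <- streams[[1L]]$timestamps
  for (s in streams[-1L])
    if (length(s$timestamps) != length(ts0) ||
        max(abs(s$timestamps - ts0)) > 1e-9)
      stop("streams are not synchronized (timestamps differ); run synchronize() first")
  rate <- streams[[1L]]$sampling_rate_hz
  n_win <- as.integer(round(window_s * rate))
  if (abs(n_win - window_s * rate) > 1e-6)
    stop("window_s * sampling rate must be an integer number of samples")
  stride_n <- as.integer(round((window_s - overlap_s) * rate))
  if (stride_n < 1L) stop("configuration error: stride shorter than one sample")
  mat <- do.call(cbind, lapply(streams, `[[`, "values"))
  axis_labels <- do.call(rbind, lapply(streams, function(s)
    data.frame(device_id = s$device_id, axis = c("x", "y", "z"),
               stringsAsFactors = FALSE)))
  n_total <- length(ts0)
  eps <- 1e-9
  out <- list()
  start_idx <- 1L
  while (start_idx + n_win - 1L <= n_total) {
    t_start <- ts0[start_idx]
    t_end <- t_start + window_s
    hit <- which(labels$start - eps <= t_start & t_end <= labels$end + eps)
    if (length(hit) >= 1L) {
      idx <- start_idx:(start_idx + n_win - 1L)
      out[[length(out) + 1L]] <- signal_window(
        samples = mat[idx, , drop = FALSE],
        axis_labels = axis_labels,
        label = labels$label[hit[1L]],
        subject_id = subject_id,
        window_start_s = t_start,
        sampling_rate_hz = rate)
    }
    start_idx <- start_idx + stride_n
  }
  out
}

#' Persist windows as per-window arrays plus a manifest
#'
#' Each window is written as a small CSV of its sample matrix; a tab-separated
#' `manifest.tsv` (one line per window) records file, subject, label, start
#' time and sampling rate.
#'
#' @param windows List of [signal_window()] objects.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    fname <- sprintf("%s_%s_%07.0f.csv", w$subject_id, w$label,
                     w$window_start_s * 1000)
    m <- w$samples
    colnames(m) <- paste(w$axis_labels$device_id, w$axis_labels$axis, sep = "_")
    utils::write.csv(m, file.path(dir, fname), row.names = FALSE)
    rows[[i]] <- data.frame(file = fname, subject = w$subject_id,
                            label = w$label, start_s = w$window_start_s,
                            rate_hz = w$sampling_rate_hz,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}
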