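# Encoders: signal window -> activity image.
#
# The central encoder splits each min-max normalized, 4-decimal signal value
# v into three decimal digit fields — integer part, first two decimals, next
# two decimals — stored in the R, G and B channels of one pixel. The split is
# exactly invertible, so the image carries the normalized signal without loss.

ENCODER_NAMES <- c("iss2image", "multichannel", "rawplot", "spectrogram",
                   "recurrence")

# round half away from zero at 4 decimals; plain round() is half-to-even
round4 <- function(x) sign(x) * floor(abs(x) * 1e4 + 0.5) / 1e4

#' Construct an activity image
#'
#' An `activity_image` is an H x W x 3 array of integer pixel values in
#' \[0, 255\] plus provenance metadata (encoder name and the source window's
#' label/subject/start). Row index is time (origin top-left), column index is
#' axis or stream, depending on the encoder.
#'
#' @param pixels H x W x 3 numeric array of integers in \[0, 255\].
#' @param encoder_name One of `"iss2image"`, `"multichannel"`, `"rawplot"`,
#'   `"spectrogram"`, `"recurrence"`.
#' @param meta List with `label`, `subject_id`, `window_start_s` (may hold
#'   further encoder-specific entries).
#' @return An object of class `activity_image`.
#' @export
activity_image <- function(pixels, encoder_name, meta = list()) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  if (any(pixels < 0) || any(pixels > 255) || any(pixels != floor(pixels)))
    stop("pixel values must be integers in [0, 255]")
  structure(list(pixels = pixels, encoder_name = encoder_name, meta = meta),
            class = "activity_image")
}

#' @export
print.activity_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<activity_image> %d x %d x 3 [%s] label=%s subject=%s\n",
              d[1L], d[2L], x$encoder_name,
              x$meta$label %||% "?", x$meta$subject_id %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max normalize a window to the \[0, 255\] pixel range
#'
#' Each axis column is mapped affinely so that its minimum becomes 0 and its
#' maximum 255, then rounded (half away from zero) to exactly four decimal
#' places — the precision the digit-splitting pixel map preserves. With
#' `scope = "per_window"` the min/max are taken over the window itself; with
#' `scope = "global"` they are supplied per axis (e.g. training-set
#' statistics), and values are clamped into \[0, 255\] after mapping.
#'
#' A degenerate axis (max equal to min) is mapped to all zeros and recorded
#' in the `degenerate_axes` attribute, with a warning.
#'
#' @param window A [signal_window()].
#' @param scope `"per_window"` (default) or `"global"`.
#' @param global_stats For `scope = "global"`: list with numeric vectors
#'   `min` and `max` of length C.
#' @return A list of class `normalized_window` with elements `values`
#'   (N x C, four-decimal values in \[0, 255\]), `axis_labels`, and the source
#'   window metadata.
#' @export
normalize_window <- function(window, scope = c("per_window", "global"),
                             global_stats = NULL) {
  scope <- match.arg(scope)
  x <- window$samples
  if (scope == "global") {
    if (is.null(global_stats) ||
        length(global_stats$min) != ncol(x) ||
        length(global_stats$max) != ncol(x))
      stop("scope='global' requires global_stats$min/max for every axis column")
    mn <- global_stats$min; mx <- global_stats$max
  } else {
    mn <- apply(x, 2L, min); mx <- apply(x, 2L, max)
  }
  rng <- mx - mn
  degenerate <- which(rng <= 0)
  rng[degenerate] <- 1
  v <- sweep(sweep(x, 2L, mn, "-"), 2L, rng, "/") * 255
  v[, degenerate] <- 0
  if (scope == "global") v <- pmin(pmax(v, 0), 255)
  if (length(degenerate))
    warning("degenerate axis (max == min) mapped to 0: column(s) ",
            paste(degenerate, collapse = ", "))
  v <- round4(v)
  structure(list(values = v, axis_labels = window$axis_labels,
                 label = window$label, subject_id = window$subject_id,
                 window_start_s = window$window_start_s,
                 sampling_rate_hz = window$sampling_rate_hz,
                 degenerate_axes = degenerate),
            class = "normalized_window")
}

#' Split a normalized value into R, G, B digit fields
#'
#' Maps a value v in \[0, 255\] carrying at most four decimal places to the
#' integer triple (integer part, first two decimal digits, next two decimal
#' digits). The digits are extracted by exact integer arithmetic on
#' `round(v * 10^4)`, which coincides with the floor-based digit extraction
#' for every four-decimal input but is immune to binary floating-point
#' representation error (e.g. 181.6508 * 100 evaluating just below 18165).
#'
#' @param v Numeric vector of values in \[0, 255\] with at most 4 decimals.
#' @return For a single value, a named integer vector `c(R=, G=, B=)`;
#'   otherwise an n x 3 integer matrix with columns R, G, B. Always
#'   R in \[0, 255\], G in \[0, 99\], B in \[0, 99\].
#' @examples
#' pixel_map(158.9812)  # 158, 98, 12
#' pixel_map(181.6508)  # 181, 65,  8
#' @export
pixel_map <- function(v) {
  if (any(v < 0) || any(v > 255))
    stop("range error: normalized values must lie in [0, 255]")
  k <- floor(v * 1e4 + 0.5)
  r <- k %/% 10000L
  g <- (k %% 10000L) %/% 100L
  b <- k %% 100L
  if (length(v) == 1L)
    return(c(R = as.integer(r), G = as.integer(g), B = as.integer(b)))
  m <- cbind(R = r, G = g, B = b)
  storage.mode(m) <- "integer"
  m
}

#' Encode a window as a digit-split RGB image (Iss2Image)
#'
#' Normalizes the window to \[0, 255\] at four-decimal precision and maps each
#' value to one pixel via [pixel_map()]: the red channel holds the integer
#' part, green the first two decimal digits, blue the next two. The image has
#' one row per time sample and one column per axis, so a 3 s window at 50 Hz
#' from two triaxial streams yields a 150 x 6 x 3 image. The encoding is
#' lossless: [iss2image_decode()] recovers the normalized window exactly.
#'
#' @inheritParams normalize_window
#' @return An [activity_image()] with `encoder_name = "iss2image"`.
#' @export
iss2image_encode <- function(window, scope = "per_window", global_stats = NULL) {
  nw <- normalize_window(window, scope, global_stats)
  v <- nw$values
  k <- floor(v * 1e4 + 0.5)
  px <- array(c(k %/% 10000L, (k %% 10000L) %/% 100L, k %% 100L),
              dim = c(nrow(v), ncol(v), 3L))
  activity_image(px, "iss2image",
                 meta = list(label = nw$label, subject_id = nw$subject_id,
                             window_start_s = nw$window_start_s))
}

#' Decode an Iss2Image back to its normalized window
#'
#' Inverse of [iss2image_encode()]: each pixel (R, G, B) becomes
#' R + G/100 + B/10000. For images produced by the encoder this reproduces
#' the four-decimal normalized values exactly.
#'
#' @param image An [activity_image()] produced by [iss2image_encode()].
#' @return A matrix of four-decimal values in \[0, 255\] (N x C).
#' @export
iss2image_decode <- function(image) {
  px <- image$pixels
  if (any(px[, , 2L] >= 100) || any(px[, , 3L] >= 100))
    stop("malformed image: G/B channels must hold two-digit fields (< 100)")
  # reassemble the 4-decimal integer first so the division matches the
  # encoder's rounding arithmetic bit for bit
  (px[, , 1L] * 10000 + px[, , 2L] * 100 + px[, , 3L]) / 10000
}

#' Encode a window as a multichannel (integer-only) RGB image
#'
#' Baseline encoder: each triaxial sample (x, y, z) becomes one pixel whose
#' R, G, B channels are the normalized values rounded to the nearest
#' integer — only the integer part of the signal survives. Height is the
#' number of time samples; width is the number of triaxial streams.
#'
#' @inheritParams normalize_window
#' @return An [activity_image()] with `encoder_name = "multichannel"`.
#' @export
multichannel_encode <- function(window, scope = "per_window",
                                global_stats = NULL) {
  C <- ncol(window$samples)
  if (C %% 3L != 0L)
    stop("configuration error: column count must be divisible by 3")
  nw <- normalize_window(window, scope, global_stats)
  n_streams <- C %/% 3L
  v <- floor(nw$values + 0.5)  # nearest integer, half away from zero
  px <- array(0, dim = c(nrow(v), n_streams, 3L))
  for (s in seq_len(n_streams))
    px[, s, ] <- v[, (3L * (s - 1L) + 1L):(3L * s)]
  activity_image(px, "multichannel",
                 meta = list(label = nw$label, subject_id = nw$subject_id,
                             window_start_s = nw$window_start_s))
}

# integer Bresenham segment; returns cbind(row, col)
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- dc + dr + 1L
  rows <- integer(n); cols <- integer(n)
  r <- r0; cc <- c0
  for (i in seq_len(n)) {
    rows[i] <- r; cols[i] <- cc
    if (r == r1 && cc == c1) { rows <- rows[1:i]; cols <- cols[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; cc <- cc + sc }
    if (e2 <  dc) { err <- err + dc; r  <- r + sr }
  }
  cbind(rows, cols)
}

#' Encode a window as a raw signal plot image
#'
#' Baseline encoder: each axis is drawn as a black polyline on a white
#' canvas, in its own horizontal band (bands stacked top to bottom in axis
#' order), amplitude normalized per axis to the band height, time mapped
#' across the canvas width. Rasterization uses Bresenham line drawing, so the
#' output is a deterministic function of the window. The result is grayscale
#' (three equal channels).
#'
#' @param window A [signal_window()].
#' @param canvas_h,canvas_w Canvas size in pixels (default 150 x 150).
#' @return An [activity_image()] with `encoder_name = "rawplot"`.
#' @export
rawplot_encode <- function(window, canvas_h = 150L, canvas_w = 150L) {
  if (canvas_h < 2L || canvas_w < 2L)
    stop("configuration error: canvas must be at least 2 x 2")
  x <- window$samples
  n <- nrow(x); C <- ncol(x)
  band_h <- canvas_h %/% C
  if (band_h < 2L)
    stop("configuration error: canvas height too small for ", C, " axis bands")
  canvas <- matrix(255, canvas_h, canvas_w)
  cols <- if (n == 1L) rep(1L, 1L) else
    as.integer(round((seq_len(n) - 1L) * (canvas_w - 1L) / (n - 1L))) + 1L
  for (j in seq_len(C)) {
    top <- (j - 1L) * band_h + 1L
    v <- x[, j]
    rng <- max(v) - min(v)
    yfrac <- if (rng > 0) (v - min(v)) / rng else rep(0.5, n)
    rows <- top + as.integer(round((1 - yfrac) * (band_h - 1L)))
    canvas[rows[1L], cols[1L]] <- 0
    if (n > 1L) for (i in seq_len(n - 1L)) {
      seg <- bresenham(rows[i], cols[i], rows[i + 1L], cols[i + 1L])
      canvas[seg] <- 0
    }
  }
  activity_image(array(canvas, dim = c(canvas_h, canvas_w, 3L)), "rawplot",
                 meta = list(label = window$label,
                             subject_id = window$subject_id,
                             window_start_s = window$window_start_s))
}

#' Encode a window as a stacked squared-STFT spectrogram image
#'
#' Baseline encoder: each axis is short-time Fourier transformed on a Hann
#' window, the squared magnitude is taken, log10(power + eps) is computed,
#' the per-axis time-frequency maps are stacked vertically (frequency
#' ascending downward within each band), and the whole image is min-max
#' scaled to \[0, 255\]. Grayscale (three equal channels).
#'
#' @param window A [signal_window()].
#' @param stft_window STFT segment length in samples (default 64).
#' @param stft_overlap Overlap between segments in samples (default 32).
#' @param eps Additive floor inside the log (default 1e-12).
#' @return An [activity_image()] with `encoder_name = "spectrogram"`.
#' @export
spectrogram_encode <- function(window, stft_window = 64L, stft_overlap = 32L,
                               eps = 1e-12) {
  x <- window$samples
  if (stft_window > nrow(x))
    stop("configuration error: stft_window exceeds the window length")
  if (stft_overlap >= stft_window)
    stop("configuration error: stft_overlap must be smaller than stft_window")
  bands <- lapply(seq_len(ncol(x)), function(j) {
    sg <- signal::specgram(x[, j], n = stft_window,
                           Fs = window$sampling_rate_hz,
                           window = signal::hanning(stft_window),
                           overlap = stft_overlap)
    log10(Mod(sg$S)^2 + eps)
  })
  img <- do.call(rbind, bands)
  rng <- max(img) - min(img)
  img <- if (rng > 0) (img - min(img)) / rng * 255 else img * 0
  img <- floor(img + 0.5)
  activity_image(array(img, dim = c(nrow(img), ncol(img), 3L)), "spectrogram",
                 meta = list(label = window$label,
                             subject_id = window$subject_id,
                             window_start_s = window$window_start_s,
                             freq_bins_per_axis = nrow(bands[[1L]])))
}

#' Encode a window as a recurrence plot image
#'
#' Baseline encoder: the N x N matrix of Euclidean distances between the full
#' C-dimensional samples at each pair of time points, min-max scaled to
#' \[0, 255\]. Periodic structure appears as near-zero off-diagonal bands at
#' the period offset. Grayscale (three equal channels).
#'
#' @param window A [signal_window()].
#' @return An [activity_image()] with `encoder_name = "recurrence"`.
#' @export
recurrence_encode <- function(window) {
  n <- nrow(window$samples)
  if (n < 2L) stop("configuration error: need at least 2 samples")
  D <- as.matrix(stats::dist(window$samples))
  rng <- max(D)
  img <- if (rng > 0) D / rng * 255 else D
  img <- floor(img + 0.5)
  activity_image(array(img, dim = c(n, n, 3L)), "recurrence",
                 meta = list(label = window$label,
                             subject_id = window$subject_id,
                             window_start_s = window$window_start_s))
}

#' Encode a window with a named encoder
#'
#' Dispatches to one of the five encoders by name, passing encoder-specific
#' parameters from `params`.
#'
#' @param window A [signal_window()].
#' @param encoder Encoder name; one of `"iss2image"`, `"multichannel"`,
#'   `"rawplot"`, `"spectrogram"`, `"recurrence"`.
#' @param params Named list of encoder parameters (`scope`, `global_stats`,
#'   `canvas_h`, `canvas_w`, `stft_window`, `stft_overlap`).
#' @return An [activity_image()].
#' @export
encode_window <- function(window, encoder, params = list()) {
  if (!encoder %in% ENCODER_NAMES)
    stop("configuration error: unknown encoder '", encoder,
         "'; valid encoders are: ", paste(ENCODER_NAMES, collapse = ", "))
  p <- function(name, default) params[[name]] %||% default
  switch(encoder,
    iss2image = iss2image_encode(window, p("scope", "per_window"),
                                 params$global_stats),
    multichannel = multichannel_encode(window, p("scope", "per_window"),
                                       params$global_stats),
    rawplot = rawplot_encode(window, p("canvas_h", 150L), p("canvas_w", 150L)),
    spectrogram = spectrogram_encode(window, p("stft_window", 64L),
                                     p("stft_overlap", 32L)),
    recurrence = recurrence_encode(window))
}

#' Write an activity image as a lossless PNG
#'
#' Only PNG output is supported: the green and blue channels of the
#' digit-split encoding carry decimal digits, so any lossy format would
#' corrupt the signal. Writing to a non-`.png` path is an error.
#'
#' @param image An [activity_image()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_activity_image <- function(image, path) {
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop("images must be written losslessly: only .png output is supported")
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read an activity image from a PNG written by [write_activity_image()]
#'
#' @param path PNG path.
#' @param encoder_name Encoder recorded in the returned object.
#' @param meta Metadata list to attach.
#' @return An [activity_image()].
#' @export
read_activity_image <- function(path, encoder_name = "iss2image",
                                meta = list()) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 3L))
  activity_image(round(px[, , 1:3] * 255), encoder_name, meta)
}

#' Encode a list of windows and write PNGs plus a manifest
#'
#' File names follow `<subject>_<label>_<start_ms>_<encoder>.png`; the
#' tab-separated manifest maps each file to its subject, label and start
#' time.
#'
#' @param windows List of [signal_window()] objects.
#' @param encoder Encoder name (see [encode_window()]).
#' @param dir Output directory.
#' @param params Encoder parameter list.
#' @return Path to the written `manifest.tsv`, invisibly.
#' @export
encode_windows <- function(windows, encoder, dir, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    img <- encode_window(windows[[i]], encoder, params)
    w <- windows[[i]]
    fname <- sprintf("%s_%s_%07.0f_%s.png", w$subject_id, w$label,
                     w$window_start_s * 1000, encoder)
    write_activity_image(img, file.path(dir, fname))
    rows[[i]] <- data.frame(file = fname, subject = w$subject_id,
                            label = w$label, start_s = w$window_start_s,
                            encoder = encoder, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}
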