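test_that("min-max normalization maps axis extremes to 0 and 255", {
  w <- make_window(cbind(c(0, 5, 10), c(-1, 0, 1), c(7, 8, 9)))
  nw <- normalize_window(w)
  expect_equal(nw$values[, 1], c(0, 127.5, 255))
  expect_equal(nw$values[c(1, 3), 2], c(0, 255))
  expect_true(all(nw$values >= 0 & nw$values <= 255))
})

test_that("a constant axis maps to zeros with a degeneracy flag", {
  w <- make_window(cbind(c(7, 7, 7), c(0, 1, 2), c(0, 1, 2)))
  expect_warning(nw <- normalize_window(w), "degenerate")
  expect_equal(nw$values[, 1], c(0, 0, 0))
  expect_equal(nw$degenerate_axes, 1L)
})

test_that("normalized values are rounded half away from zero to four decimals", {
  # raw values chosen so the affine map is the identity (min 0, max 255)
  w <- make_window(rbind(c(0, 0, 0), c(158.98123001, 21.43215, 9.99995),
                         c(255, 255, 255)))
  nw <- normalize_window(w)
  expect_identical(nw$values[2, ], c(158.9812, 21.4322, 10))
  expect_equal(nw$values * 1e4, round(nw$values * 1e4))
})

test_that("global normalization scope uses supplied statistics and clamps", {
  w <- make_window(cbind(c(1, 2, 3), c(0, 5, 12), c(0, 1, 2)))
  gs <- list(min = c(0, 0, 0), max = c(10, 10, 10))
  nw <- normalize_window(w, scope = "global", global_stats = gs)
  expect_equal(nw$values[, 1], round(c(1, 2, 3) / 10 * 255, 4))
  expect_equal(nw$values[3, 2], 255)  # 12 clamps to the top of the range
  expect_error(normalize_window(w, scope = "global"), "global_stats")
})

test_that("pixel map splits integer and decimal digit pairs", {
  expect_identical(pixel_map(158.9812), c(R = 158L, G = 98L, B = 12L))
  expect_identical(pixel_map(181.6508), c(R = 181L, G = 65L, B = 8L))
  expect_identical(pixel_map(112.2935), c(R = 112L, G = 29L, B = 35L))
  expect_identical(pixel_map(0), c(R = 0L, G = 0L, B = 0L))
  expect_identical(pixel_map(255), c(R = 255L, G = 0L, B = 0L))
  expect_error(pixel_map(-0.1), "range error")
  expect_error(pixel_map(255.1), "range error")
  m <- pixel_map(c(1.02, 254.9999))
  expect_identical(m, cbind(R = c(1L, 254L), G = c(2L, 99L), B = c(0L, 99L)))
})

test_that("digit-split encoding has the lossless round-trip property", {
  set.seed(7)
  # >= 1e4 random 4-decimal values in [0, 255] plus the boundary grid
  v <- c(round(runif(12000, 0, 255), 4), 0, 255, 0.0001, 254.9999)
  m <- matrix(v[seq_len(length(v) %/% 3 * 3)], ncol = 3)
  m[1, ] <- 0; m[2, ] <- 255                 # pin the per-axis extremes
  w <- make_window(m)
  img <- iss2image_encode(w)
  expect_true(all(img$pixels[, , 1] >= 0 & img$pixels[, , 1] <= 255))
  expect_true(all(img$pixels[, , 2] >= 0 & img$pixels[, , 2] <= 99))
  expect_true(all(img$pixels[, , 3] >= 0 & img$pixels[, , 3] <= 99))
  dec <- iss2image_decode(img)
  expect_identical(dec, unname(normalize_window(w)$values))
})

test_that("decode inverts the worked digit triples and rejects malformed pixels", {
  px <- array(c(158, 98, 12), dim = c(1, 1, 3))
  expect_equal(as.vector(iss2image_decode(activity_image(px, "iss2image"))),
               158.9812)
  bad <- array(c(1, 150, 0), dim = c(1, 1, 3))
  expect_error(iss2image_decode(activity_image(bad, "iss2image")),
               "malformed")
})

test_that("digit-split images have one row per sample and one column per axis", {
  w6 <- make_window(matrix(rnorm(150 * 6), 150, 6))
  expect_equal(dim(iss2image_encode(w6)$pixels), c(150L, 6L, 3L))
  w3 <- make_window(matrix(rnorm(50 * 3), 50, 3))
  img3 <- iss2image_encode(w3)
  expect_equal(dim(img3$pixels), c(50L, 3L, 3L))
  expect_equal(length(img3$pixels), 450L)  # one second at 50 Hz, one stream
})

test_that("R channel is the floor of the normalized values; multichannel rounds", {
  w <- make_window(matrix(rnorm(60 * 6), 60, 6))
  nw <- normalize_window(w)
  iss <- iss2image_encode(w)
  expect_equal(iss$pixels[, , 1], floor(unname(nw$values)))
  mc <- multichannel_encode(w)
  expect_equal(dim(mc$pixels), c(60L, 2L, 3L))
  rounded <- floor(unname(nw$values) + 0.5)
  for (s in 1:2)
    expect_equal(mc$pixels[, s, ], rounded[, (3 * s - 2):(3 * s)])
})

test_that("multichannel turns one normalized triaxial sample into one rgb pixel", {
  # identity affine map again: extremes pinned at 0 and 255
  m <- rbind(c(0, 0, 0), c(255, 255, 255), c(158.9812, 181.6508, 112.2935))
  mc <- multichannel_encode(make_window(m))
  expect_equal(as.vector(mc$pixels[3, 1, ]), c(159, 182, 112))
  w_bad <- structure(list(samples = matrix(0, 4, 4)), class = "signal_window")
  expect_error(multichannel_encode(w_bad), "divisible by 3")
})

test_that("raw signal plot draws one horizontal line per axis band for constant input", {
  w <- make_window(matrix(0, 50, 3))
  img <- rawplot_encode(w, 150, 150)
  expect_equal(dim(img$pixels), c(150L, 150L, 3L))
  expect_equal(img$pixels[, , 1], img$pixels[, , 2])
  expect_equal(img$pixels[, , 1], img$pixels[, , 3])
  g <- img$pixels[, , 1]
  dark_rows <- which(apply(g, 1, function(r) any(r == 0)))
  expect_length(dark_rows, 3L)                      # one line per band
  expect_true(all(g[dark_rows, ] == 0))             # full-width lines
  expect_true(all(g[-dark_rows, ] == 255))
})

test_that("raw signal plot is deterministic and validates its canvas", {
  w <- make_window(matrix(sin(1:300), 100, 3))
  expect_identical(rawplot_encode(w)$pixels, rawplot_encode(w)$pixels)
  expect_error(rawplot_encode(w, 1, 150), "configuration error")
})

test_that("spectrogram peaks at the bin nearest a pure tone", {
  rate <- 50; n <- 150; nfft <- 64
  f0 <- 8 * rate / nfft                      # exactly bin 8: 6.25 Hz
  t <- (0:(n - 1)) / rate
  w <- make_window(cbind(sin(2 * pi * f0 * t), sin(2 * pi * f0 * t),
                         cos(2 * pi * f0 * t)), rate_hz = rate)
  img <- spectrogram_encode(w, stft_window = nfft, stft_overlap = 32)
  bins <- img$meta$freq_bins_per_axis
  for (ax in 1:3) {
    band <- img$pixels[(ax - 1) * bins + seq_len(bins), , 1, drop = FALSE]
    expect_equal(unname(apply(band[, , 1, drop = FALSE], 2, which.max)),
                 rep(9, ncol(band)))          # 1-based: bin 8 is row 9
  }
})

test_that("constant signal concentrates spectrogram energy in the DC bin", {
  w <- make_window(matrix(5, 150, 3))
  img <- spectrogram_encode(w)
  bins <- img$meta$freq_bins_per_axis
  for (ax in 1:3) {
    band <- img$pixels[(ax - 1) * bins + seq_len(bins), , 1, drop = FALSE]
    expect_equal(unname(apply(band[, , 1, drop = FALSE], 2, which.max)),
                 rep(1, ncol(band)))
  }
  expect_error(spectrogram_encode(make_window(matrix(1:30, 10, 3))),
               "configuration error")
})

test_that("recurrence plot is a scaled symmetric distance matrix", {
  w <- make_window(matrix(rnorm(40 * 3), 40, 3))
  img <- recurrence_encode(w)
  g <- img$pixels[, , 1]
  expect_equal(dim(g), c(40L, 40L))
  expect_equal(g, t(g))
  expect_true(all(diag(g) == 0))
  expect_equal(max(g), 255)
  # constant window: degenerate scaling maps everything to 0
  expect_true(all(recurrence_encode(make_window(matrix(1, 10, 3)))$pixels == 0))
  expect_error(recurrence_encode(make_window(matrix(0, 1, 3))),
               "configuration error")
})

test_that("recurrence plot exposes the period of a periodic signal", {
  rate <- 50; p <- 25                        # 2 Hz tone: period 25 samples
  t <- (0:149) / rate
  w <- make_window(cbind(sin(2 * pi * 2 * t), cos(2 * pi * 2 * t),
                         sin(2 * pi * 2 * t + 1)), rate_hz = rate)
  D <- as.matrix(dist(w$samples))
  for (i in seq_len(150 - p))
    expect_lt(D[i, i + p], D[i, i + p / 2])
})

test_that("every encoder is a pure deterministic function of its inputs", {
  w <- make_window(matrix(rnorm(150 * 6), 150, 6))
  for (enc in c("iss2image", "multichannel", "rawplot", "spectrogram",
                "recurrence"))
    expect_identical(encode_window(w, enc)$pixels, encode_window(w, enc)$pixels)
  expect_error(encode_window(w, "wavelet"),
               "iss2image, multichannel, rawplot, spectrogram, recurrence")
})

test_that("png round trip is bit-exact and lossy formats are refused", {
  w <- make_window(matrix(rnorm(50 * 6), 50, 6))
  img <- iss2image_encode(w)
  f <- withr::local_tempfile(fileext = ".png")
  write_activity_image(img, f)
  back <- read_activity_image(f)
  expect_equal(back$pixels, img$pixels)
  expect_error(write_activity_image(img, sub("png$", "jpg", f)), "lossless")
})
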