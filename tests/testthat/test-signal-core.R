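test_that("load_recording returns one stream per declared pair and preserves rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(f, n = 300)
  streams <- load_recording(f, two_stream_schema())
  expect_length(streams, 2L)
  expect_equal(vapply(streams, function(s) length(s$timestamps), 1L),
               c(300L, 300L))
  expect_equal(attr(streams, "dropped_rows"), 0L)
  expect_equal(streams[[1]]$device_id, "phone")
  expect_equal(streams[[2]]$values[, "z"], -streams[[1]]$values[, "z"])
})

test_that("rows with unparseable values are dropped and counted", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(f, n = 100, bad_rows = 37L)
  streams <- load_recording(f, two_stream_schema())
  expect_equal(length(streams[[1]]$timestamps), 99L)
  expect_equal(attr(streams, "dropped_rows"), 1L)
})

test_that("schema and empty-file errors are raised", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(f)
  bad <- two_stream_schema()
  bad$streams[[2]]$cols <- c("wx", "wy", "nope")
  expect_error(load_recording(f, bad), "schema error.*nope")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,px,py,pz,wx,wy,wz", f2)
  expect_error(load_recording(f2, two_stream_schema()), "empty")
})

test_that("synchronizing an already-uniform stream at its own rate is the identity", {
  s <- make_stream(n = 200, rate = 50)
  out <- synchronize(list(s), 50)
  expect_lt(max(abs(out[[1]]$values - s$values)), 1e-9)
  expect_lt(max(abs(out[[1]]$timestamps - s$timestamps)), 1e-12)
})

test_that("mixed-rate streams land on the uniform grid over the overlap", {
  a <- make_stream("phone", n = 1000, rate = 100, t0 = 0)     # spans [0, 9.99]
  b <- make_stream("watch", n = 400, rate = 50, t0 = 2)       # spans [2, 9.98]
  out <- synchronize(list(a, b), 50)
  # independent count: uniform grid points in [2, 9.98] at 50 Hz
  expected_n <- floor((9.98 - 2) * 50) + 1
  expect_equal(length(out[[1]]$timestamps), expected_n)
  expect_equal(out[[1]]$timestamps, out[[2]]$timestamps)
  expect_equal(diff(out[[1]]$timestamps), rep(1 / 50, expected_n - 1))
})

test_that("disjoint time spans raise a synchronization error", {
  a <- make_stream("phone", n = 100, rate = 50, t0 = 0)
  b <- make_stream("watch", n = 100, rate = 50, t0 = 100)
  expect_error(synchronize(list(a, b), 50), "synchronization error")
})

test_that("60 s at 50 Hz with 3 s windows and 1 s overlap yields 29 windows of 150 x C", {
  streams <- list(make_stream("phone", n = 3000, rate = 50),
                  make_stream("watch", n = 3000, rate = 50))
  labels <- data.frame(start = 0, end = 60, label = "walk")
  wins <- segment_windows(streams, 3, 1, labels)
  expect_length(wins, 29L)
  expect_equal(dim(wins[[1]]$samples), c(150L, 6L))
  expect_equal(vapply(wins, `[[`, 0, "window_start_s"), seq(0, 56, by = 2))
})

test_that("window counts and contents match brute-force enumeration", {
  # independent oracle: enumerate every candidate start index directly
  brute_force <- function(n_total, rate, window_s, overlap_s) {
    n_win <- round(window_s * rate)
    stride <- round((window_s - overlap_s) * rate)
    starts <- integer(0)
    i <- 1L
    repeat {
      if (i + n_win - 1L > n_total) break
      starts <- c(starts, i)
      i <- i + stride
    }
    starts
  }
  set.seed(101)
  for (rep in 1:20) {
    rate <- sample(c(20, 25, 50), 1)
    dur <- sample(5:40, 1)
    window_s <- sample(c(1, 2, 3, 4), 1)
    overlap_s <- window_s * sample(c(0, 0.25, 0.5, 0.75), 1)
    if (dur < window_s) next
    n <- dur * rate
    s <- make_stream(n = n, rate = rate,
                     gen = function(t) matrix(rnorm(3 * length(t)), ncol = 3))
    labels <- data.frame(start = 0, end = dur, label = "a")
    wins <- segment_windows(list(s), window_s, overlap_s, labels)
    starts <- brute_force(n, rate, window_s, overlap_s)
    expect_length(wins, length(starts))
    # conservation: emitted samples are bit-identical slices of the stream
    k <- sample(length(wins), 1)
    idx <- starts[k]:(starts[k] + round(window_s * rate) - 1L)
    expect_identical(unname(wins[[k]]$samples), unname(s$values[idx, ]))
  }
})

test_that("a recording exactly one window long yields exactly one window", {
  s <- make_stream(n = 150, rate = 50)
  wins <- segment_windows(list(s), 3, 1,
                          data.frame(start = 0, end = 3, label = "a"))
  expect_length(wins, 1L)
})

test_that("windows straddling a label boundary are discarded", {
  s <- make_stream(n = 500, rate = 50)  # 10 s
  labels <- data.frame(start = c(0, 5), end = c(5, 10), label = c("a", "b"))
  wins <- segment_windows(list(s), 3, 1, labels)
  # starts 0, 2 fit in [0,5); 4 straddles; 6 fits in [5,10); never 8 (ends 11)
  expect_equal(vapply(wins, `[[`, 0, "window_start_s"), c(0, 2, 6))
  expect_equal(vapply(wins, `[[`, "", "label"), c("a", "a", "b"))
})

test_that("overlap >= window is a configuration error", {
  s <- make_stream(n = 300, rate = 50)
  labels <- data.frame(start = 0, end = 6, label = "a")
  expect_error(segment_windows(list(s), 3, 3, labels), "configuration error")
})
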