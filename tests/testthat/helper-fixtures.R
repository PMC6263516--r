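# Shared fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a signal_window wrapping an N x C matrix directly
make_window <- function(values, rate_hz = 50, label = "walk",
                        subject_id = "S01", start = 0) {
  values <- as.matrix(values)
  n_streams <- ncol(values) / 3L
  axis_labels <- do.call(rbind, lapply(seq_len(n_streams), function(s)
    data.frame(device_id = paste0("dev", s), axis = c("x", "y", "z"),
               stringsAsFactors = FALSE)))
  signal_window(values, axis_labels, label, subject_id, start, rate_hz)
}

# uniform triaxial stream with deterministic values
make_stream <- function(device_id = "phone", n = 300, rate = 50, t0 = 0,
                        gen = function(t) cbind(sin(t), cos(t), t)) {
  t <- t0 + (seq_len(n) - 1) / rate
  sensor_stream(device_id, "accelerometer", t, gen(t), sampling_rate_hz = rate)
}

# write a two-stream recording CSV; optionally corrupt some rows
write_recording_csv <- function(path, n = 300, rate = 50, bad_rows = integer(0)) {
  t <- (seq_len(n) - 1) / rate
  df <- data.frame(t = t, px = sin(t), py = cos(t), pz = t,
                   wx = sin(2 * t), wy = cos(2 * t), wz = -t)
  dfc <- as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE)
  for (r in bad_rows) dfc$px[r] <- "not-a-number"
  utils::write.csv(dfc, path, row.names = FALSE, quote = FALSE)
  path
}

two_stream_schema <- function() {
  list(time_col = "t",
       streams = list(
         list(device_id = "phone", sensor_kind = "accelerometer",
              cols = c("px", "py", "pz")),
         list(device_id = "watch", sensor_kind = "accelerometer",
              cols = c("wx", "wy", "wz"))))
}

# tiny fast-training scenario: 2 classes, 2 subjects, short windows
tiny_scenario <- function(seed = 42L, subjects = 2L, duration = 16) {
  classes <- list(
    activity_class_spec("shake", base_freq_hz = 5, amplitude = 2,
                        gravity_offset = c(0, 0, 9.81), noise_sd = 0.2,
                        freq_jitter = 0.02),
    activity_class_spec("rest", base_freq_hz = 0.5, amplitude = 0.05,
                        gravity_offset = c(1, 0, 9.7), noise_sd = 0.2,
                        freq_jitter = 0.02))
  recs <- simulate_recording(classes, subjects = subjects, streams = 2L,
                             duration_s_per_class = duration, rate_hz = 25,
                             seed = seed)
  windows_from_recordings(recs, window_s = 1.28, overlap_s = 0.64)
}
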