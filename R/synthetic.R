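# Synthetic multi-subject inertial recordings.
#
# Each activity class is a quasi-periodic triaxial signal: per axis an
# amplitude-scaled sinusoid at a class-specific cadence, a constant gravity/
# posture offset, and additive Gaussian noise. Subjects differ by a random
# relative perturbation of the class frequency and by random phases, which
# is what makes leave-one-subject-out evaluation non-trivial.

#' Define an activity class for the simulator
#'
#' @param name Class label.
#' @param base_freq_hz Dominant (cadence) frequency in Hz; must lie below the
#'   Nyquist frequency of the simulated rate.
#' @param amplitude Sinusoid amplitude per axis (length 3, recycled from a
#'   scalar), in signal units (m/s^2 for accelerometer-like streams).
#' @param gravity_offset Constant offset per axis (length 3), emulating the
#'   gravity/posture component.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param freq_jitter Per-subject relative frequency jitter: each subject's
#'   realized frequency is `base_freq_hz * (1 + u)`, u uniform in
#'   \[-freq_jitter, freq_jitter\].
#' @return An object of class `activity_class_spec`.
#' @export
activity_class_spec <- function(name, base_freq_hz, amplitude = 1,
                                gravity_offset = c(0, 0, 9.81),
                                noise_sd = 0.3, freq_jitter = 0.05) {
  stopifnot(base_freq_hz > 0, noise_sd >= 0, freq_jitter >= 0)
  structure(list(name = as.character(name), base_freq_hz = base_freq_hz,
                 amplitude = rep_len(amplitude, 3L),
                 gravity_offset = rep_len(gravity_offset, 3L),
                 noise_sd = noise_sd, freq_jitter = freq_jitter),
            class = "activity_class_spec")
}

#' Default four-class benchmark scenario classes
#'
#' Four classes chosen to span the separability structure of daily-activity
#' recordings: a near-static posture ("still"), two gait classes of
#' different cadence and energy ("walk" ~1.8 Hz, "run" ~2.8 Hz), and a
#' slow large-amplitude household motion with a tilted posture ("sweep").
#' Amplitudes and offsets are in m/s^2.
#'
#' @return List of [activity_class_spec()] objects.
#' @export
default_activity_classes <- function() {
  list(
    activity_class_spec("still", base_freq_hz = 0.25,
                        amplitude = c(0.02, 0.02, 0.02),
                        gravity_offset = c(0.3, -0.2, 9.81),
                        noise_sd = 0.05, freq_jitter = 0.05),
    activity_class_spec("walk", base_freq_hz = 1.8,
                        amplitude = c(1.5, 1.0, 2.5),
                        gravity_offset = c(0.5, 0.1, 9.81),
                        noise_sd = 0.3, freq_jitter = 0.06),
    activity_class_spec("run", base_freq_hz = 2.8,
                        amplitude = c(4, 3, 6),
                        gravity_offset = c(0.8, 0.2, 9.81),
                        noise_sd = 0.5, freq_jitter = 0.06),
    activity_class_spec("sweep", base_freq_hz = 0.9,
                        amplitude = c(3, 2, 1),
                        gravity_offset = c(4, 1, 8.5),
                        noise_sd = 0.4, freq_jitter = 0.08))
}

#' Simulate labeled multi-subject, multi-device recordings
#'
#' For every subject, the classes are performed back to back for
#' `duration_s_per_class` seconds each. Each axis of each stream is
#' `a * sin(2*pi*f_s*t + phi) + g + N(0, sd^2)` where `f_s` is the subject's
#' jittered class frequency and `phi` a random phase per stream and axis.
#' The generator is fully determined by `seed`.
#'
#' @param classes List of [activity_class_spec()] objects (at least 2).
#' @param subjects Number of subjects (default 6).
#' @param streams Number of triaxial streams (devices) per subject
#'   (default 2; the first two are named `"phone"` and `"watch"`).
#' @param duration_s_per_class Seconds of signal per class per subject
#'   (default 60).
#' @param rate_hz Sampling rate in Hz (default 50).
#' @param seed Integer seed for the pseudo-random generator.
#' @return List with one element per subject, each a list with
#'   `subject_id`, `streams` (list of [sensor_stream()]), and `labels`
#'   (data frame of half-open labeled intervals `start`, `end`, `label`).
#' @export
simulate_recording <- function(classes, subjects = 6L, streams = 2L,
                               duration_s_per_class = 60, rate_hz = 50,
                               seed = 42L) {
  if (length(classes) < 2L) stop("need at least 2 activity classes")
  for (cl in classes)
    if (cl$base_freq_hz >= rate_hz / 2)
      stop("configuration error: class '", cl$name,
           "' frequency is at or above the Nyquist frequency")
  set.seed(seed)
  device_names <- c("phone", "watch",
                    sprintf("dev%02d", seq_len(max(0L, streams - 2L)) + 2L))
  device_names <- device_names[seq_len(streams)]
  n_per_class <- as.integer(round(duration_s_per_class * rate_hz))
  total_n <- n_per_class * length(classes)
  t_all <- (seq_len(total_n) - 1L) / rate_hz
  lapply(seq_len(subjects), function(s) {
    subject_id <- sprintf("S%02d", s)
    freqs <- vapply(classes, function(cl)
      cl$base_freq_hz * (1 + stats::runif(1, -cl$freq_jitter, cl$freq_jitter)),
      0)
    stream_vals <- lapply(seq_len(streams), function(d) {
      vals <- matrix(0, total_n, 3L)
      for (k in seq_along(classes)) {
        cl <- classes[[k]]
        rows <- ((k - 1L) * n_per_class + 1L):(k * n_per_class)
        tt <- t_all[rows]
        for (ax in 1:3) {
          phi <- stats::runif(1, 0, 2 * pi)
          vals[rows, ax] <- cl$amplitude[ax] * sin(2 * pi * freqs[k] * tt + phi) +
            cl$gravity_offset[ax] +
            if (cl$noise_sd > 0) stats::rnorm(length(tt), 0, cl$noise_sd) else 0
        }
      }
      vals
    })
    labels <- data.frame(
      start = (seq_along(classes) - 1L) * duration_s_per_class,
      end = seq_along(classes) * duration_s_per_class,
      label = vapply(classes, `[[`, "", "name"),
      stringsAsFactors = FALSE)
    list(subject_id = subject_id,
         streams = lapply(seq_len(streams), function(d)
           sensor_stream(device_names[d], "accelerometer", t_all,
                         stream_vals[[d]], sampling_rate_hz = rate_hz)),
         labels = labels)
  })
}

#' Write a simulated recording set as delimited text
#'
#' One CSV per subject (`<subject>.csv`, columns `t` then
#' `<device>_x/_y/_z` per stream), one label file per subject
#' (`<subject>_labels.csv`), and a `schema.yaml` describing the column
#' layout in the format [load_recording()] consumes.
#'
#' @param recordings Output of [simulate_recording()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_recordings <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  schema <- list(time_col = "t",
                 streams = lapply(recordings[[1L]]$streams, function(st)
                   list(device_id = st$device_id, sensor_kind = st$sensor_kind,
                        cols = paste(st$device_id, c("x", "y", "z"), sep = "_"))))
  yaml::write_yaml(schema, file.path(dir, "schema.yaml"))
  for (rec in recordings) {
    df <- data.frame(t = rec$streams[[1L]]$timestamps)
    for (st in rec$streams) {
      m <- st$values
      colnames(m) <- paste(st$device_id, c("x", "y", "z"), sep = "_")
      df <- cbind(df, m)
    }
    utils::write.csv(df, file.path(dir, paste0(rec$subject_id, ".csv")),
                     row.names = FALSE)
    utils::write.csv(rec$labels,
                     file.path(dir, paste0(rec$subject_id, "_labels.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Segment a simulated recording set into labeled windows
#'
#' Convenience wrapper: synchronizes each subject's streams at their common
#' rate and applies [segment_windows()].
#'
#' @param recordings Output of [simulate_recording()].
#' @param window_s,overlap_s Window length and overlap in seconds.
#' @return List of [signal_window()] objects over all subjects.
#' @export
windows_from_recordings <- function(recordings, window_s = 3, overlap_s = 1) {
  out <- list()
  for (rec in recordings) {
    rate <- rec$streams[[1L]]$sampling_rate_hz
    ws <- segment_windows(rec$streams, window_s, overlap_s, rec$labels,
                          subject_id = rec$subject_id)
    out <- c(out, ws)
  }
  out
}
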