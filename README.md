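# iss2har

Human activity recognition (HAR) from wearable inertial sensors —
accelerometers and gyroscopes in phones and watches — hinges on turning raw
triaxial signals into a representation a classifier can exploit.
Convolutional networks want images; most signal-to-image transforms (line
plots, spectrograms, recurrence plots) distort or discard the original
values on the way. `iss2har` implements a *lossless-by-construction*
encoding: each windowed signal value is min-max normalized to [0, 255],
rounded to four decimals, and split into three decimal digit fields

    R = ⌊v⌋      G = first two decimal digits      B = next two decimal digits

so one sensor value becomes one RGB pixel and the image is exactly
invertible (`v = R + G/100 + B/10000`). A 3 s window at 50 Hz from two
triaxial devices becomes a 150 × 6 × 3 image: rows are time samples, columns
are the x, y, z axes of each device. The package pairs the encoder with
**UCNet6**, a compact CNN — six 3×3 convolutions alternating 64/128 filters,
each followed by batch normalization and ReLU, with two 2×2/stride-2
max-pools and a softmax head — trained by SGD with momentum (initial rate
0.1, divided by 10 every 15 epochs, mini-batches of 128).

For whom: anyone building or benchmarking image-based HAR pipelines who
wants the encoding, the four standard baseline encoders (multichannel
integer encoding, raw signal plot, spectrogram, recurrence plot), and an
end-to-end reproducible evaluation harness without downloading any dataset.

The package covers the full chain:

* `load_recording()`, `synchronize()`, `segment_windows()` — delimited-text
  recordings → synchronized streams → labeled fixed-width windows (3 s
  window / 1 s overlap by default).
* `iss2image_encode()` / `iss2image_decode()`, `multichannel_encode()`,
  `rawplot_encode()`, `spectrogram_encode()`, `recurrence_encode()` —
  window → image; PNG-only persistence (`write_activity_image()`), since a
  lossy format would corrupt the digit channels.
* `simulate_recording()` — multi-subject, multi-device synthetic recordings
  with class-distinct quasi-periodic structure (sinusoid + gravity offset +
  Gaussian noise, per-subject cadence jitter).
* `build_ucnet6()`, `train_ucnet6()`, `predict_ucnet6()` — the classifier,
  with compiled (Rcpp + BLAS) layer kernels.
* `evaluate()`, `loso_splits()`, `run_loso()` — confusion matrices, overall
  and macro accuracy, leave-one-subject-out protocol.
* `run_pipeline()` and `inst/cli/iss2har.R` — the
  simulate → encode → train → evaluate chain as a library call or shell
  command.

## Worked example

```r
library(iss2har)

# the digit-splitting pixel map on a normalized value
pixel_map(158.9812)
#>   R   G   B
#> 158  98  12

# simulate the 4-class benchmark scenario: 6 subjects, phone + watch, 50 Hz
recs <- simulate_recording(default_activity_classes(), subjects = 6,
                           streams = 2, duration_s_per_class = 60,
                           rate_hz = 50, seed = 42)
wins <- windows_from_recordings(recs, window_s = 3, overlap_s = 1)
length(wins)                      # 696 windows (29 per class per subject)

img <- iss2image_encode(wins[[1]])
dim(img$pixels)                   # 150 6 3
all(iss2image_decode(img) == normalize_window(wins[[1]])$values)  # TRUE

# train UCNet6 on the encoded images (stratified 70/30 split)
labels <- vapply(wins, `[[`, "", "label")
model  <- build_ucnet6(ucnet6_spec(150, 6, num_classes = 4), seed = 42)
model  <- train_ucnet6(model, lapply(wins, iss2image_encode), labels,
                       train_config(epochs = 8, seed = 42))
tail(model$history$val_accuracy, 1)
#> [1] 0.9759615
```

Held-out accuracy on this synthetic scenario is ~0.98 for the digit-split
encoding and ~0.99 for the multichannel baseline (the two are within the
noise of each other here; the scenario is deliberately separable — see the
methods vignette for what this does and does not show).

The same run from a shell:

```sh
Rscript inst/cli/iss2har.R all --seed 42 --encoder iss2image --out run/
```

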