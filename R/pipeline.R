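# End-to-end pipeline: simulate -> encode -> train -> evaluate.
#
# Every stage reads the previous stage's on-disk artifacts and writes its
# own, so the stages can be run separately (as the CLI does) or chained with
# stage = "all". Each run writes an effective-config stamp for
# reproducibility.

#' Pipeline configuration
#'
#' Defaults reproduce the benchmark scenario: 4 synthetic activity classes,
#' 6 subjects, 2 triaxial streams at 50 Hz, 60 s per class, 3 s windows with
#' 1 s overlap, digit-split encoding, and the UCNet6 training recipe.
#'
#' @param out_dir Output directory for all artifacts.
#' @param classes List of [activity_class_spec()]; defaults to
#'   [default_activity_classes()].
#' @param subjects,streams,duration_s_per_class,rate_hz Simulation scenario.
#' @param window_s,overlap_s Sliding-window segmentation parameters
#'   (seconds).
#' @param encoder Encoder name (see [encode_window()]).
#' @param encoder_params Encoder parameter list.
#' @param train Training configuration, a [train_config()].
#' @param split `"stratified"` (default) or `"loso"`; LOSO trains one model
#'   per held-out subject and pools the test predictions.
#' @param seed Master seed for simulation (training uses `train$seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "iss2har_run",
                            classes = default_activity_classes(),
                            subjects = 6L, streams = 2L,
                            duration_s_per_class = 60, rate_hz = 50,
                            window_s = 3, overlap_s = 1,
                            encoder = "iss2image", encoder_params = list(),
                            train = train_config(), split = "stratified",
                            seed = 42L) {
  if (!encoder %in% ENCODER_NAMES)
    stop("configuration error: unknown encoder '", encoder,
         "'; valid encoders are: ", paste(ENCODER_NAMES, collapse = ", "))
  if (overlap_s >= window_s)
    stop("configuration error: overlap_s must be smaller than window_s")
  structure(list(out_dir = out_dir, classes = classes,
                 subjects = as.integer(subjects), streams = as.integer(streams),
                 duration_s_per_class = duration_s_per_class, rate_hz = rate_hz,
                 window_s = window_s, overlap_s = overlap_s,
                 encoder = encoder, encoder_params = encoder_params,
                 train = train, split = split, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `classes` is a
#' list of mappings with the [activity_class_spec()] fields and `train` a
#' mapping with the [train_config()] fields. Omitted keys keep their
#' defaults. `overrides` (e.g. from CLI flags) take precedence.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list overriding file keys.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  raw[names(overrides)] <- overrides
  args <- list()
  direct <- intersect(names(raw),
                      c("out_dir", "subjects", "streams",
                        "duration_s_per_class", "rate_hz", "window_s",
                        "overlap_s", "encoder", "encoder_params", "split",
                        "seed"))
  args[direct] <- raw[direct]
  if (!is.null(raw$classes))
    args$classes <- lapply(raw$classes, function(cl) do.call(activity_class_spec, cl))
  if (!is.null(raw$train))
    args$train <- do.call(train_config, raw$train)
  do.call(pipeline_config, args)
}

pipeline_paths <- function(config) {
  root <- config$out_dir
  list(root = root,
       recordings = file.path(root, "recordings"),
       images = file.path(root, "images"),
       model = file.path(root, "model"),
       checkpoint = file.path(root, "model", "ucnet6.rds"),
       history = file.path(root, "model", "history.tsv"),
       report = file.path(root, "eval_report.json"),
       config_stamp = file.path(root, "effective_config.yaml"))
}

stamp_config <- function(config, paths) {
  dir.create(paths$root, showWarnings = FALSE, recursive = TRUE)
  plain <- rapply(unclass(config), function(x)
    if (is.list(x)) x else as.vector(x), how = "replace")
  yaml::write_yaml(plain, paths$config_stamp)
}

pipeline_simulate <- function(config, paths) {
  recs <- simulate_recording(config$classes, config$subjects, config$streams,
                             config$duration_s_per_class, config$rate_hz,
                             seed = config$seed)
  write_recordings(recs, paths$recordings)
  message("simulate: wrote ", length(recs), " subject recordings to ",
          paths$recordings)
  recs
}

pipeline_load_windows <- function(config, paths) {
  schema_path <- file.path(paths$recordings, "schema.yaml")
  if (!file.exists(schema_path))
    stop("missing upstream artifact: ", schema_path,
         " (run the simulate stage first)")
  schema <- yaml::read_yaml(schema_path)
  files <- sort(list.files(paths$recordings, pattern = "^S\\d+\\.csv$",
                           full.names = TRUE))
  windows <- list()
  for (f in files) {
    subject <- sub("\\.csv$", "", basename(f))
    streams <- load_recording(f, schema)
    streams <- synchronize(streams, config$rate_hz)
    labels <- utils::read.csv(file.path(paths$recordings,
                                        paste0(subject, "_labels.csv")),
                              stringsAsFactors = FALSE)
    windows <- c(windows, segment_windows(streams, config$window_s,
                                          config$overlap_s, labels,
                                          subject_id = subject))
  }
  windows
}

pipeline_encode <- function(config, paths) {
  windows <- pipeline_load_windows(config, paths)
  mpath <- encode_windows(windows, config$encoder, paths$images,
                          config$encoder_params)
  message("encode: wrote ", length(windows), " ", config$encoder,
          " images to ", paths$images)
  mpath
}

pipeline_read_images <- function(config, paths) {
  mpath <- file.path(paths$images, "manifest.tsv")
  if (!file.exists(mpath))
    stop("missing upstream artifact: ", mpath, " (run the encode stage first)")
  manifest <- utils::read.table(mpath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(manifest)), function(i)
    read_activity_image(file.path(paths$images, manifest$file[i]),
                        encoder_name = manifest$encoder[i],
                        meta = list(label = manifest$label[i],
                                    subject_id = manifest$subject[i],
                                    window_start_s = manifest$start_s[i])))
  list(images = images, manifest = manifest)
}

pipeline_train <- function(config, paths) {
  im <- pipeline_read_images(config, paths)
  d <- dim(im$images[[1L]]$pixels)
  spec <- ucnet6_spec(d[1L], d[2L],
                      num_classes = length(unique(im$manifest$label)))
  model <- build_ucnet6(spec, seed = config$train$seed)
  split <- NULL
  if (identical(config$split, "loso"))
    stop("use run_loso() for leave-one-subject-out evaluation")
  model <- train_ucnet6(model, im$images, im$manifest$label, config$train,
                        split = split, verbose = TRUE)
  dir.create(paths$model, showWarnings = FALSE, recursive = TRUE)
  save_ucnet6(model, paths$checkpoint)
  utils::write.table(model$history, paths$history, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  message("train: checkpoint at ", paths$checkpoint)
  model
}

pipeline_evaluate <- function(config, paths) {
  if (!file.exists(paths$checkpoint))
    stop("missing upstream artifact: ", paths$checkpoint,
         " (run the train stage first)")
  model <- load_ucnet6(paths$checkpoint)
  im <- pipeline_read_images(config, paths)
  idx <- model$split$val
  if (!length(idx)) idx <- seq_along(im$images)
  pred <- predict_ucnet6(model, im$images[idx])
  report <- evaluate(im$manifest$label[idx], pred$labels,
                     class_names = model$class_names)
  write_eval_report(report, paths$report)
  print(report)
  message("evaluate: report at ", paths$report)
  report
}

#' Run the pipeline
#'
#' Executes one stage (`"simulate"`, `"encode"`, `"train"`, `"evaluate"`) or
#' the full chain (`"all"`). Each stage writes its artifacts under
#' `config$out_dir` and later stages read them from there, so stages can be
#' re-run independently.
#'
#' @param config A [pipeline_config()].
#' @param stage Stage name.
#' @return The evaluation report for `"evaluate"`/`"all"`, otherwise the
#'   stage's main artifact, invisibly.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "encode",
                                           "train", "evaluate")) {
  stage <- match.arg(stage)
  paths <- pipeline_paths(config)
  stamp_config(config, paths)
  out <- switch(stage,
    simulate = pipeline_simulate(config, paths),
    encode = pipeline_encode(config, paths),
    train = pipeline_train(config, paths),
    evaluate = pipeline_evaluate(config, paths),
    all = {
      pipeline_simulate(config, paths)
      pipeline_encode(config, paths)
      pipeline_train(config, paths)
      pipeline_evaluate(config, paths)
    })
  invisible(out)
}

#' Leave-one-subject-out evaluation of an encoder + UCNet6
#'
#' Trains one model per subject fold (training on all other subjects,
#' validating on a stratified slice of the training fold is skipped — the
#' fold's own test subject is the held-out set) and pools the per-fold test
#' predictions into a single report.
#'
#' @param windows List of labeled [signal_window()] objects.
#' @param encoder Encoder name.
#' @param encoder_params Encoder parameter list.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with the pooled `report` and per-fold accuracies
#'   `fold_accuracy`.
#' @export
run_loso <- function(windows, encoder = "iss2image", encoder_params = list(),
                     cfg = train_config(), verbose = FALSE) {
  images <- lapply(windows, encode_window, encoder = encoder,
                   params = encoder_params)
  labels <- vapply(windows, `[[`, "", "label")
  folds <- loso_splits(windows)
  d <- dim(images[[1L]]$pixels)
  spec <- ucnet6_spec(d[1L], d[2L], num_classes = length(unique(labels)))
  truth <- character(0); pred <- character(0)
  fold_acc <- numeric(0)
  for (s in names(folds)) {
    fold <- folds[[s]]
    model <- build_ucnet6(spec, seed = cfg$seed)
    model <- train_ucnet6(model, images[fold$train], labels[fold$train], cfg,
                          split = list(train = seq_along(fold$train),
                                       val = integer(0)),
                          verbose = verbose)
    p <- predict_ucnet6(model, images[fold$test])
    truth <- c(truth, labels[fold$test])
    pred <- c(pred, p$labels)
    fold_acc[s] <- mean(p$labels == labels[fold$test])
  }
  list(report = evaluate(truth, pred, sort(unique(labels))),
       fold_accuracy = fold_acc)
}
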