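# UCNet6: a compact six-convolution CNN for activity-image classification.
#
# Three blocks of {conv(64) -> BN -> ReLU -> conv(128) -> BN -> ReLU}; the
# first two blocks are followed by a 2x2/stride-2 max pool (there is no pool
# after the third block), then a single fully connected layer to the class
# scores and a softmax. All convolutions are 3x3, stride 1, padding 1.

#' Describe a UCNet6 model
#'
#' @param input_height,input_width Input image size in pixels. The time axis
#'   (height) must survive two floor-halving poolings, so
#'   `input_height >= 4`. A width of 1 is allowed: a pooled spatial
#'   dimension of size 1 is passed through unchanged.
#' @param num_classes Number of activity classes (>= 2).
#' @param input_channels Number of image channels; fixed at 3.
#' @return An object of class `ucnet6_spec`.
#' @export
ucnet6_spec <- function(input_height, input_width, num_classes,
                        input_channels = 3L) {
  if (input_channels != 3L) stop("input_channels must be 3 (RGB images)")
  if (num_classes < 2L) stop("num_classes must be at least 2")
  if (input_height < 4L || input_width < 1L)
    stop("configuration error: input too small for two pooling stages")
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 input_channels = 3L,
                 num_classes = as.integer(num_classes)),
            class = "ucnet6_spec")
}

ucnet6_layer_defs <- function() {
  conv <- function(name, filters) list(type = "conv", name = name,
                                       filters = filters, kernel = 3L,
                                       stride = 1L, padding = 1L)
  bn <- function(name) list(type = "bn", name = name)
  relu <- function() list(type = "relu", name = "relu")
  pool <- function(name) list(type = "maxpool", name = name, kernel = 2L,
                              stride = 2L, padding = 0L)
  list(conv("conv1", 64L), bn("bn1"), relu(),
       conv("conv2", 128L), bn("bn2"), relu(),
       pool("maxpool1"),
       conv("conv3", 64L), bn("bn3"), relu(),
       conv("conv4", 128L), bn("bn4"), relu(),
       pool("maxpool2"),
       conv("conv5", 64L), bn("bn5"), relu(),
       conv("conv6", 128L), bn("bn6"), relu(),
       list(type = "fc", name = "fc"))
}

ucnet6_init_params <- function(spec) {
  layers <- ucnet6_layer_defs()
  params <- list()
  bn_stats <- list()
  Cin <- spec$input_channels
  H <- spec$input_height; W <- spec$input_width
  for (l in layers) {
    if (l$type == "conv") {
      sd <- sqrt(2 / (Cin * l$kernel^2))     # He initialization for ReLU nets
      params[[l$name]] <- list(
        W = array(stats::rnorm(l$filters * Cin * 9L, sd = sd),
                  dim = c(l$filters, Cin, 3L, 3L)),
        b = numeric(l$filters))
      Cin <- l$filters
    } else if (l$type == "bn") {
      params[[l$name]] <- list(gamma = rep(1, Cin), beta = numeric(Cin))
      bn_stats[[l$name]] <- list(mu = numeric(Cin), var = rep(1, Cin))
    } else if (l$type == "maxpool") {
      H <- pool_out_dim(H); W <- pool_out_dim(W)
    } else if (l$type == "fc") {
      fan_in <- Cin * H * W
      sd <- sqrt(2 / (fan_in + spec$num_classes))  # Glorot for the linear head
      params$fc <- list(
        W = matrix(stats::rnorm(spec$num_classes * fan_in, sd = sd),
                   spec$num_classes, fan_in),
        b = numeric(spec$num_classes))
    }
  }
  list(params = params, bn_stats = bn_stats, fc_in = Cin * H * W,
       feature_dims = c(Cin, H, W))
}

#' Build a UCNet6 model
#'
#' Instantiates the layer sequence with randomly initialized weights (He
#' initialization for the convolutions, Glorot for the linear head). The
#' built model is immediately usable for forward passes; [train_ucnet6()]
#' re-initializes from its own seed so that training is reproducible from
#' the training configuration alone.
#'
#' @param spec A [ucnet6_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `ucnet6`.
#' @export
build_ucnet6 <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ucnet6_spec"))
  set.seed(seed)
  ini <- ucnet6_init_params(spec)
  structure(list(spec = spec, layers = ucnet6_layer_defs(),
                 params = ini$params, bn_stats = ini$bn_stats,
                 fc_in = ini$fc_in, feature_dims = ini$feature_dims,
                 mean_image = NULL, class_names = NULL, trained = FALSE,
                 history = NULL),
            class = "ucnet6")
}

#' Tabulate the convolution and pooling layers of a built model
#'
#' Walks the model's layer sequence and reports, for every convolutional and
#' max-pooling layer, the number of filters, kernel/pooling size, stride and
#' padding.
#'
#' @param model A [build_ucnet6()] model.
#' @return Data frame with columns `layer`, `n_filters`, `size`, `stride`,
#'   `padding`.
#' @export
architecture_table <- function(model) {
  rows <- Filter(function(l) l$type %in% c("conv", "maxpool"), model$layers)
  data.frame(
    layer = vapply(rows, `[[`, "", "name"),
    n_filters = vapply(rows, function(l)
      if (l$type == "conv") l$filters else NA_integer_, 1L),
    size = vapply(rows, `[[`, 1L, "kernel"),
    stride = vapply(rows, `[[`, 1L, "stride"),
    padding = vapply(rows, `[[`, 1L, "padding"),
    stringsAsFactors = FALSE)
}

#' @export
print.ucnet6 <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<ucnet6> input %dx%dx3, %d classes, %s\n", s$input_height,
              s$input_width, s$num_classes,
              if (x$trained) "trained" else "untrained"))
  print(architecture_table(x))
  invisible(x)
}

# Forward pass. X: (3, H, W, B), already mean-centered/scaled by the caller.
# mode "train" uses batch statistics in the BN layers and returns caches for
# backprop; "infer" uses the stored population statistics. Every BN layer in
# this architecture is followed by a ReLU, and the pair is executed as one
# fused kernel; its cache lives at the BN layer's position.
ucnet6_forward <- function(model, X, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  caches <- if (mode == "train") vector("list", length(model$layers)) else NULL
  A <- X
  i <- 1L
  while (i <= length(model$layers)) {
    l <- model$layers[[i]]
    P <- model$params[[l$name]]
    if (l$type == "conv") {
      if (mode == "train") caches[[i]] <- list(X = A)
      A <- conv_forward(A, P$W, P$b)
    } else if (l$type == "bn") {
      stopifnot(model$layers[[i + 1L]]$type == "relu")
      if (mode == "train") {
        st <- bn_batch_stats(A)
        Y <- bn_relu_fwd_cpp(A, dim(A)[1L], P$gamma, P$beta, st$mu, st$invstd)
        caches[[i]] <- list(X = A, mu = st$mu, invstd = st$invstd,
                            var = st$var, Y = Y)
        A <- Y
      } else {
        rs <- model$bn_stats[[l$name]]
        A <- bn_relu_fwd_cpp(A, dim(A)[1L], P$gamma, P$beta, rs$mu,
                             1 / sqrt(rs$var + 1e-5))
      }
      i <- i + 1L  # the fused kernel consumed the following relu
    } else if (l$type == "maxpool") {
      if (mode == "train") caches[[i]] <- list(X = A)
      A <- maxpool_forward(A)
    } else if (l$type == "fc") {
      if (mode == "train") caches[[i]] <- list(X = A)
      A <- fc_forward(A, P$W, P$b)
    }
    i <- i + 1L
  }
  list(logits = A, caches = caches)
}

ucnet6_backward <- function(model, caches, dlogits) {
  grads <- list()
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    P <- model$params[[l$name]]
    cc <- caches[[i]]
    if (l$type == "fc") {
      g <- fc_backward(d, cc$X, P$W)
      grads$fc <- list(W = g$dW, b = g$db)
      d <- g$dX
    } else if (l$type == "relu") {
      # handled by the fused kernel at the preceding bn layer
    } else if (l$type == "bn") {
      g <- relu_bn_bwd_cpp(d, cc$X, cc$Y, dim(cc$X)[1L], P$gamma, cc$mu,
                           cc$invstd)
      grads[[l$name]] <- list(gamma = g$dgamma, beta = g$dbeta)
      d <- g$dX
    } else if (l$type == "conv") {
      g <- conv_backward(d, cc$X, P$W, want_dx = i > 1L)
      grads[[l$name]] <- list(W = g$dW, b = g$db)
      d <- g$dX
    } else if (l$type == "maxpool") {
      d <- maxpool_backward(d, cc$X)
    }
  }
  grads
}

#' Training configuration for UCNet6
#'
#' Defaults follow UCNet6's standard training recipe: SGD with momentum 0.9, 45 epochs,
#' mini-batch size 128, initial learning rate 0.1 divided by 10 every 15
#' epochs.
#'
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param lr_drop_factor Factor by which the rate is divided at each drop.
#' @param lr_drop_every_epochs Epoch period of the drops.
#' @param momentum SGD momentum coefficient.
#' @param seed Integer seed driving initialization and shuffling.
#' @param validation_split Held-out fraction for the default stratified
#'   split.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 45L, batch_size = 128L, initial_lr = 0.1,
                         lr_drop_factor = 10, lr_drop_every_epochs = 15L,
                         momentum = 0.9, seed = 42L,
                         validation_split = 0.3) {
  stopifnot(epochs > 0, batch_size > 0, initial_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_drop_every_epochs = as.integer(lr_drop_every_epochs),
                 momentum = momentum, seed = as.integer(seed),
                 validation_split = validation_split),
            class = "train_config")
}

#' Learning rate at a given epoch under the step schedule
#'
#' `initial_lr / lr_drop_factor^floor((epoch - 1) / lr_drop_every_epochs)`:
#' 0.1 at epoch 1, 0.01 at epoch 16, 0.001 at epoch 31 under the defaults.
#'
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch number.
#' @return The learning rate.
#' @export
lr_schedule <- function(cfg, epoch) {
  cfg$initial_lr / cfg$lr_drop_factor^((epoch - 1L) %/% cfg$lr_drop_every_epochs)
}

#' Stratified train/validation split
#'
#' @param labels Vector of class labels, one per example.
#' @param val_fraction Fraction of each class held out for validation.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
stratified_split <- function(labels, val_fraction = 0.3, seed = 42L) {
  set.seed(seed)
  val <- integer(0)
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  val <- sort(val)
  list(train = setdiff(seq_along(labels), val), val = val)
}

images_to_array <- function(images, spec = NULL) {
  if (is.list(images) && length(images) &&
      inherits(images[[1L]], "activity_image"))
    images <- lapply(images, `[[`, "pixels")
  n <- length(images)
  if (n == 0L) return(array(0, c(3L, 0L, 0L, 0L)))
  d <- dim(images[[1L]])
  X <- array(0, c(3L, d[1L], d[2L], n))
  for (i in seq_len(n)) {
    p <- images[[i]]
    if (!identical(dim(p), d)) stop("images have inconsistent dimensions")
    X[, , , i] <- aperm(p, c(3L, 1L, 2L))
  }
  if (!is.null(spec) &&
      (d[1L] != spec$input_height || d[2L] != spec$input_width))
    stop("image size ", d[1L], "x", d[2L],
         " does not match the model input ", spec$input_height, "x",
         spec$input_width)
  X
}

#' Train a UCNet6 model
#'
#' Minimizes the softmax cross-entropy with SGD plus momentum under the step
#' learning-rate schedule of `cfg`. All randomness (weight initialization,
#' split, shuffling) is driven by `cfg$seed`; the same seed and data yield a
#' bit-identical model. Inputs are mean-centered with the training-set mean
#' image and scaled by 1/255 before entering the network. After the last
#' epoch the batch-norm population statistics are finalized with one pass
#' over the training set.
#'
#' @param model A [build_ucnet6()] model.
#' @param images List of [activity_image()] objects (or H x W x 3 arrays).
#' @param labels Class label per image.
#' @param cfg A [train_config()].
#' @param split Optional list with integer indices `train` and `val`;
#'   defaults to a stratified split by label
#'   (fraction `cfg$validation_split`, seed `cfg$seed`).
#' @param verbose Print one line per epoch.
#' @return The trained model, with `$history` (data frame of epoch,
#'   learning rate, training loss, validation accuracy) attached.
#' @export
train_ucnet6 <- function(model, images, labels, cfg = train_config(),
                         split = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ucnet6"))
  labels <- as.character(labels)
  class_names <- sort(unique(labels))
  X <- images_to_array(images, model$spec)
  if (length(labels) != dim(X)[4L])
    stop("number of labels must match number of images")
  if (is.null(split))
    split <- stratified_split(labels, cfg$validation_split, cfg$seed)
  if (length(unique(labels[split$train])) < 2L)
    stop("training set must contain at least 2 classes")
  y_all <- match(labels, class_names)

  set.seed(cfg$seed)
  ini <- ucnet6_init_params(model$spec)
  model$params <- ini$params
  model$bn_stats <- ini$bn_stats
  model$class_names <- class_names

  mean_image <- apply(X[, , , split$train, drop = FALSE], 1:3, mean)
  model$mean_image <- mean_image
  center <- function(idx) {
    Z <- X[, , , idx, drop = FALSE]
    (Z - as.vector(mean_image)) / 255
  }

  vel <- rapply(model$params, function(p) p * 0, how = "replace")
  n_train <- length(split$train)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_accuracy = numeric(0))

  infer_accuracy <- function(idx) {
    if (!length(idx)) return(NA_real_)
    correct <- 0L
    for (bi in split(idx, ceiling(seq_along(idx) / 256))) {
      out <- ucnet6_forward(model, center(bi), mode = "infer")
      pred <- apply(out$logits, 2L, which.max)
      correct <- correct + sum(pred == y_all[bi])
    }
    correct / length(idx)
  }

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(cfg, epoch)
    order_idx <- split$train[sample.int(n_train)]
    batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      out <- ucnet6_forward(model, center(idx), mode = "train")
      sx <- softmax_xent(out$logits, y_all[idx])
      losses[bi] <- sx$loss
      grads <- ucnet6_backward(model, out$caches, sx$dlogits)
      for (nm in names(grads)) {
        for (pn in names(grads[[nm]])) {
          vel[[nm]][[pn]] <- cfg$momentum * vel[[nm]][[pn]] -
            lr * grads[[nm]][[pn]]
          model$params[[nm]][[pn]] <- model$params[[nm]][[pn]] +
            vel[[nm]][[pn]]
        }
      }
      for (i in seq_along(model$layers)) {     # running BN statistics
        l <- model$layers[[i]]
        if (l$type == "bn") {
          cc <- out$caches[[i]]
          rs <- model$bn_stats[[l$name]]
          model$bn_stats[[l$name]] <- list(
            mu = 0.9 * rs$mu + 0.1 * cc$mu,
            var = 0.9 * rs$var + 0.1 * cc$var)
        }
      }
    }
    val_acc <- infer_accuracy(split$val)
    history[nrow(history) + 1L, ] <- list(epoch, lr, mean(losses), val_acc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  loss %.4f  val acc %s", epoch, lr,
                      mean(losses),
                      if (is.na(val_acc)) "-" else sprintf("%.4f", val_acc)))
  }

  # Finalize BN population statistics over the full training set.
  for (nm in names(model$bn_stats))
    model$bn_stats[[nm]] <- list(mu = 0, var = 0)
  batches <- split(split$train, ceiling(seq_along(split$train) / cfg$batch_size))
  wts <- vapply(batches, length, 1L) / n_train
  acc_stats <- NULL
  for (bi in seq_along(batches)) {
    out <- ucnet6_forward(model, center(batches[[bi]]), mode = "train")
    for (i in seq_along(model$layers)) {
      l <- model$layers[[i]]
      if (l$type == "bn") {
        cc <- out$caches[[i]]
        rs <- model$bn_stats[[l$name]]
        model$bn_stats[[l$name]] <- list(
          mu = rs$mu + wts[bi] * cc$mu,
          var = rs$var + wts[bi] * cc$var)
      }
    }
  }
  model$trained <- TRUE
  final_val <- infer_accuracy(split$val)
  if (nrow(history)) history$val_accuracy[nrow(history)] <- final_val
  model$history <- history
  model$split <- split
  model
}

#' Predict activity labels for encoded images
#'
#' Runs the network in inference mode (population batch-norm statistics) and
#' returns the argmax class per image; ties break toward the lowest class
#' index.
#'
#' @param model A trained [train_ucnet6()] model.
#' @param images List of [activity_image()] objects or H x W x 3 arrays.
#' @return List with `labels` (character) and `probabilities`
#'   (n x num_classes row-stochastic matrix, columns named by class).
#' @export
predict_ucnet6 <- function(model, images) {
  stopifnot(inherits(model, "ucnet6"))
  if (length(images) == 0L)
    return(list(labels = character(0),
                probabilities = matrix(0, 0L, model$spec$num_classes,
                                       dimnames = list(NULL, model$class_names))))
  X <- images_to_array(images, model$spec)
  n <- dim(X)[4L]
  probs <- matrix(0, n, model$spec$num_classes,
                  dimnames = list(NULL, model$class_names))
  mean_image <- model$mean_image %||% 0
  for (bi in split(seq_len(n), ceiling(seq_len(n) / 256))) {
    Z <- (X[, , , bi, drop = FALSE] - as.vector(mean_image)) / 255
    out <- ucnet6_forward(model, Z, mode = "infer")
    probs[bi, ] <- t(softmax_cols(out$logits))
  }
  idx <- max.col(probs, ties.method = "first")
  list(labels = model$class_names[idx], probabilities = probs)
}

#' Save / load a UCNet6 checkpoint
#'
#' Checkpoints are single-file R serializations of the full model object
#' (architecture, weights, batch-norm statistics, normalization constants,
#' class names, history); a save/load round trip reproduces predictions
#' exactly.
#'
#' @param model A `ucnet6` model.
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `save_ucnet6()`: `path`, invisibly. `load_ucnet6()`: the model.
#' @export
save_ucnet6 <- function(model, path) {
  stopifnot(inherits(model, "ucnet6"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ucnet6
#' @export
load_ucnet6 <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ucnet6")) stop("not a ucnet6 checkpoint: ", path)
  model
}
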