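# direct (non-GEMM) 3x3/stride-1/pad-1 convolution, the independent oracle
naive_conv3x3 <- function(X, W, b) {
  d <- dim(X); C <- d[1]; H <- d[2]; Wd <- d[3]; B <- d[4]
  Cout <- dim(W)[1]
  Y <- array(0, c(Cout, H, Wd, B))
  for (bb in 1:B) for (o in 1:Cout) for (h in 1:H) for (w in 1:Wd) {
    acc <- b[o]
    for (ky in -1:1) for (kx in -1:1) {
      hh <- h + ky; ww <- w + kx
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= Wd)
        acc <- acc + sum(W[o, , ky + 2, kx + 2] * X[, hh, ww, bb])
    }
    Y[o, h, w, bb] <- acc
  }
  Y
}

test_that("the GEMM convolution matches a direct convolution oracle", {
  set.seed(21)
  X <- array(rnorm(4 * 6 * 5 * 2), c(4, 6, 5, 2))
  W <- array(rnorm(3 * 4 * 9), c(3, 4, 3, 3))
  b <- rnorm(3)
  expect_equal(iss2har:::conv_forward(X, W, b), naive_conv3x3(X, W, b),
               tolerance = 1e-12)
})

test_that("max pooling floor-halves dimensions and passes size-1 dims through", {
  set.seed(22)
  X <- array(rnorm(2 * 7 * 6 * 2), c(2, 7, 6, 2))
  Y <- iss2har:::maxpool_forward(X)
  expect_equal(dim(Y), c(2L, 3L, 3L, 2L))
  # oracle: explicit window maxima (row 7 is dropped by the floor)
  for (b in 1:2) for (c in 1:2) for (i in 1:3) for (j in 1:3)
    expect_equal(Y[c, i, j, b],
                 max(X[c, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j), b]))
  X1 <- array(rnorm(2 * 8 * 1 * 2), c(2, 8, 1, 2))
  Y1 <- iss2har:::maxpool_forward(X1)
  expect_equal(dim(Y1), c(2L, 4L, 1L, 2L))
  expect_equal(Y1[1, , 1, 1], pmax(X1[1, seq(1, 8, 2), 1, 1],
                                   X1[1, seq(2, 8, 2), 1, 1]))
})

test_that("analytic gradients match finite differences on a small network", {
  set.seed(31)
  m <- build_ucnet6(ucnet6_spec(8, 4, num_classes = 3), seed = 3)
  X <- array(rnorm(3 * 8 * 4 * 5), c(3, 8, 4, 5))
  y <- c(1L, 2L, 3L, 1L, 2L)
  fwd <- iss2har:::ucnet6_forward
  sx <- iss2har:::softmax_xent
  loss_fn <- function(mm) sx(fwd(mm, X, "train")$logits, y)$loss
  out <- fwd(m, X, "train")
  s <- sx(out$logits, y)
  gr <- iss2har:::ucnet6_backward(m, out$caches, s$dlogits)
  eps <- 1e-5
  for (nm in c("conv1", "conv4", "conv6", "bn2", "bn5", "fc")) {
    for (pn in names(gr[[nm]])) {
      if (grepl("^conv", nm) && pn == "b") next  # exactly cancelled by BN
      p <- m$params[[nm]][[pn]]
      for (k in sample(length(p), min(4, length(p)))) {
        m2 <- m
        m2$params[[nm]][[pn]][k] <- p[k] + eps
        lp <- loss_fn(m2)
        m2$params[[nm]][[pn]][k] <- p[k] - eps
        lm <- loss_fn(m2)
        num <- (lp - lm) / (2 * eps)
        ana <- gr[[nm]][[pn]][k]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("the built model walks out as six convolutions and two pools", {
  m <- build_ucnet6(ucnet6_spec(150, 6, 4), seed = 1)
  tab <- architecture_table(m)
  expect_equal(tab$layer, c("conv1", "conv2", "maxpool1", "conv3", "conv4",
                            "maxpool2", "conv5", "conv6"))
  expect_equal(tab$n_filters, c(64L, 128L, NA, 64L, 128L, NA, 64L, 128L))
  expect_equal(tab$size, c(3L, 3L, 2L, 3L, 3L, 2L, 3L, 3L))
  expect_equal(tab$stride, c(1L, 1L, 2L, 1L, 1L, 2L, 1L, 1L))
  expect_equal(tab$padding, c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L))
  expect_equal(sum(vapply(m$layers, function(l) l$type == "conv", TRUE)), 6L)
  expect_equal(sum(vapply(m$layers, function(l) l$type == "maxpool", TRUE)), 2L)
})

test_that("a 150 x 6 input reaches the classifier as a 37 x 1 x 128 feature map", {
  m <- build_ucnet6(ucnet6_spec(150, 6, 4), seed = 1)
  expect_equal(m$feature_dims, c(128L, 37L, 1L))
  expect_equal(m$fc_in, 128L * 37L)
})

test_that("the input layer adapts to different window resolutions", {
  for (h in c(150L, 300L, 512L)) {
    m <- build_ucnet6(ucnet6_spec(h, 6, 5), seed = 2)
    X <- array(rnorm(3 * h * 6 * 2), c(3, h, 6, 2))
    out <- iss2har:::ucnet6_forward(m, X, "infer")
    p <- iss2har:::softmax_cols(out$logits)
    expect_equal(colSums(p), c(1, 1), tolerance = 1e-6)
  }
  expect_error(ucnet6_spec(3, 6, 4), "too small")
  expect_error(ucnet6_spec(150, 6, 1), "num_classes")
})

test_that("the step schedule divides the rate by 10 every 15 epochs", {
  cfg <- train_config()
  expect_equal(lr_schedule(cfg, 1), 0.1)
  expect_equal(lr_schedule(cfg, 15), 0.1)
  expect_equal(lr_schedule(cfg, 16), 0.01)
  expect_equal(lr_schedule(cfg, 31), 0.001)
})

test_that("training is reproducible, learns, and round-trips through a checkpoint", {
  wins <- tiny_scenario()
  imgs <- lapply(wins, iss2image_encode)
  labels <- vapply(wins, `[[`, "", "label")
  d <- dim(imgs[[1]]$pixels)
  spec <- ucnet6_spec(d[1], d[2], 2)
  cfg <- train_config(epochs = 10, batch_size = 32, initial_lr = 0.05,
                      lr_drop_every_epochs = 4, seed = 11)
  m1 <- train_ucnet6(build_ucnet6(spec), imgs, labels, cfg)
  m2 <- train_ucnet6(build_ucnet6(spec), imgs, labels, cfg)
  expect_identical(m1$history, m2$history)
  # training converges: the loss drops by orders of magnitude from epoch 1
  # and the finalized model separates the two classes
  expect_lt(min(m1$history$train_loss), 0.05 * m1$history$train_loss[1])
  expect_gte(tail(m1$history$val_accuracy, 1), 0.95)
  expect_equal(m1$history$lr, lr_schedule(cfg, 1:10))
  p1 <- predict_ucnet6(m1, imgs)
  expect_equal(rowSums(p1$probabilities), rep(1, length(imgs)),
               tolerance = 1e-9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_ucnet6(m1, f)
  p2 <- predict_ucnet6(load_ucnet6(f), imgs)
  expect_identical(p1, p2)
  expect_identical(predict_ucnet6(m1, list()),
                   list(labels = character(0),
                        probabilities = matrix(0, 0, 2,
                                               dimnames = list(NULL, m1$class_names))))
})

test_that("degenerate training inputs are rejected", {
  wins <- tiny_scenario(subjects = 1L, duration = 8)
  imgs <- lapply(wins, iss2image_encode)
  labels <- vapply(wins, `[[`, "", "label")
  spec <- ucnet6_spec(32, 6, 2)
  one_class <- which(labels == labels[1])
  expect_error(train_ucnet6(build_ucnet6(spec), imgs[one_class],
                            labels[one_class], train_config(epochs = 1)),
               "at least 2 classes")
  wrong <- ucnet6_spec(64, 6, 2)
  expect_error(train_ucnet6(build_ucnet6(wrong), imgs, labels,
                            train_config(epochs = 1)),
               "does not match")
})
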