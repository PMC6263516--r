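# Layer primitives for the CNN, thin R wrappers over the compiled kernels
# in src/layers.cpp.
#
# Activations are stored channel-first as (C, H, W, B) arrays so that each
# 3x3/stride-1/pad-1 convolution reduces to nine BLAS GEMMs, one per kernel
# offset, against a shifted view of the zero-padded input. All arithmetic is
# double precision.

conv_forward <- function(X, W, b)
  conv3x3_fwd_cpp(X, dim(X), W, dim(W)[1L], b)

conv_backward <- function(dY, X, W, want_dx = TRUE)
  conv3x3_bwd_cpp(dY, X, dim(X), W, dim(W)[1L], want_dx)

# Per-channel mean and biased variance over all spatial positions and batch
# items of a (C, H, W, B) activation.
bn_batch_stats <- function(X, eps = 1e-5) {
  st <- bn_stats_cpp(X, dim(X)[1L])
  st$invstd <- 1 / sqrt(st$var + eps)
  st
}

# 2x2 max pooling, stride 2, no padding; a spatial dimension of size 1 is
# passed through unchanged (the window never extends past the input), while
# dimensions >= 2 are floor-halved.
pool_out_dim <- function(d) if (d >= 2L) d %/% 2L else 1L

maxpool_forward <- function(X) maxpool_fwd_cpp(X, dim(X))

maxpool_backward <- function(dY, X) maxpool_bwd_cpp(dY, X, dim(X))

fc_forward <- function(X, W, b) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(prod(d[-4L]), d[4L])
  W %*% Xm + b
}

fc_backward <- function(dY, X, W) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(prod(d[-4L]), d[4L])
  dX <- crossprod(W, dY)
  dim(dX) <- d
  list(dX = dX, dW = tcrossprod(dY, Xm), db = rowSums(dY))
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Cross-entropy over a batch; y holds 1-based class indices.
softmax_xent <- function(logits, y) {
  p <- softmax_cols(logits)
  B <- ncol(logits)
  idx <- cbind(y, seq_len(B))
  loss <- -mean(log(p[idx] + 1e-12))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B, probs = p)
}
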