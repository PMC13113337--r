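# Convolutional autodiff operations for the image encoder.
#
# Feature maps are stored as (H*W) x C matrices (pixels column-major, channel
# per column).  Convolutions are computed as im2col gathers followed by a
# single matrix multiply; the backward pass scatters gradients through the
# same index map.  Index maps are memoized per shape.

.conv_memo <- new.env(parent = emptyenv())

# Index map: rows = output pixels, cols = k*k*C entries giving the linear
# index into the (H*W) x C input laid out as a vector, or NA for zero padding.
conv_index_map <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  got <- .conv_memo[[key]]
  if (!is.null(got)) return(got)
  H2 <- (H + 2 * pad - k) %/% stride + 1L
  W2 <- (W + 2 * pad - k) %/% stride + 1L
  i2 <- rep(seq_len(H2), times = W2)           # output row index (column-major)
  j2 <- rep(seq_len(W2), each = H2)
  # kernel offsets, row-fastest within the k x k window
  di <- rep(seq_len(k), times = k) - 1L
  dj <- rep(seq_len(k), each = k) - 1L
  ii <- outer((i2 - 1L) * stride - pad + 1L, di, "+")   # (H2*W2) x k^2
  jj <- outer((j2 - 1L) * stride - pad + 1L, dj, "+")
  lin <- ii + (jj - 1L) * H
  lin[ii < 1L | ii > H | jj < 1L | jj > W] <- NA_integer_
  if (C > 1L) {
    offs <- rep((seq_len(C) - 1L) * (H * W), each = k * k)
    lin <- lin[, rep(seq_len(k * k), C), drop = FALSE] +
      matrix(offs, nrow(lin), k * k * C, byrow = TRUE)
  }
  out <- list(map = lin, H2 = H2, W2 = W2)
  .conv_memo[[key]] <- out
  out
}

im2col <- function(xvec, map) {
  idx <- map$map
  v <- xvec[idx]
  v[is.na(as.vector(idx))] <- 0
  matrix(v, nrow(idx), ncol(idx))
}

# 2-D convolution: x is an ad node holding an (H*W) x C matrix, w a
# (k*k*C) x C_out weight (rows matching the im2col column order), b 1 x C_out.
ad_conv2d <- function(tape, x, w, b, H, W, k, stride = 1L, pad = 0L) {
  x <- ad_operand(x); w <- ad_operand(w); b <- ad_operand(b)
  C <- ncol(x$val)
  mp <- conv_index_map(H, W, C, k, stride, pad)
  P <- im2col(as.vector(x$val), mp)
  val <- sweep(P %*% w$val, 2L, b$val[1L, ], "+")
  node <- ad_node(tape, val, list(x, w, b), function(g) {
    gP <- tcrossprod(g, w$val)                       # (H2*W2) x (k^2*C)
    idx <- as.vector(mp$map)
    keep <- !is.na(idx)
    acc <- rowsum(as.vector(gP)[keep], idx[keep])
    gx <- matrix(0, H * W, C)
    gx[as.integer(rownames(acc))] <- acc
    list(gx, crossprod(P, g), matrix(colSums(g), 1L))
  })
  attr(node, "H") <- mp$H2
  attr(node, "W") <- mp$W2
  node
}

# Max pooling over k x k windows, per channel.
ad_maxpool <- function(tape, x, H, W, k, stride, pad = 0L) {
  x <- ad_operand(x)
  C <- ncol(x$val)
  mp <- conv_index_map(H, W, 1L, k, stride, pad)
  n_out <- nrow(mp$map)
  val <- matrix(0, n_out, C)
  argmax <- matrix(NA_integer_, n_out, C)
  for (c in seq_len(C)) {
    v <- x$val[, c][mp$map]
    v[is.na(as.vector(mp$map))] <- -Inf
    vm <- matrix(v, n_out)
    pick <- max.col(vm, ties.method = "first")
    val[, c] <- vm[cbind(seq_len(n_out), pick)]
    argmax[, c] <- mp$map[cbind(seq_len(n_out), pick)]
  }
  node <- ad_node(tape, val, list(x), function(g) {
    gx <- matrix(0, H * W, C)
    for (c in seq_len(C)) {
      acc <- rowsum(g[, c], argmax[, c])
      gx[as.integer(rownames(acc)), c] <- gx[as.integer(rownames(acc)), c] + acc
    }
    list(gx)
  })
  attr(node, "H") <- mp$H2
  attr(node, "W") <- mp$W2
  node
}

# Inference-mode batch normalization folded to a per-channel affine
# transform (learnable scale/shift; running statistics are identity at random
# initialization and absorbed into gamma/beta when weights are loaded).
ad_channel_affine <- function(tape, x, gamma, beta) {
  x <- ad_operand(x); gamma <- ad_operand(gamma); beta <- ad_operand(beta)
  n <- nrow(x$val)
  gm <- matrix(gamma$val[1L, ], n, ncol(x$val), byrow = TRUE)
  val <- x$val * gm + matrix(beta$val[1L, ], n, ncol(x$val), byrow = TRUE)
  ad_node(tape, val, list(x, gamma, beta), function(g) {
    list(g * gm,
         matrix(colSums(g * x$val), 1L),
         matrix(colSums(g), 1L))
  })
}
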