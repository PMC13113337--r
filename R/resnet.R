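# Bottleneck residual network (depths 50/101/152) used as the faithful
# GADF-image encoder.  The final classification layer is removed: the output
# is the 2048-dimensional global-average-pooled feature vector.
#
# Weights are randomly initialized by default; `pretrained = TRUE` attempts to
# load a checkpoint from `weights_path` and falls back to random
# initialization with a message when none is available (no download is ever
# attempted).

resnet_stage_blocks <- function(depth) {
  switch(as.character(depth),
         "50" = c(3L, 4L, 6L, 3L),
         "101" = c(3L, 4L, 23L, 3L),
         "152" = c(3L, 8L, 36L, 3L),
         abort_input("depth must be one of 50, 101, 152"))
}

init_conv <- function(k, c_in, c_out) {
  fan_in <- k * k * c_in
  list(W = ad_param(matrix(stats::rnorm(k * k * c_in * c_out, 0,
                                        sqrt(2 / fan_in)),
                           k * k * c_in, c_out)),
       b = ad_param(matrix(0, 1L, c_out)),
       k = k)
}

init_bn <- function(c_out) {
  list(gamma = ad_param(matrix(1, 1L, c_out)), beta = ad_param(matrix(0, 1L, c_out)))
}

init_bottleneck <- function(c_in, width, stride) {
  out <- width * 4L
  blk <- list(
    conv1 = init_conv(1L, c_in, width), bn1 = init_bn(width),
    conv2 = init_conv(3L, width, width), bn2 = init_bn(width),
    conv3 = init_conv(1L, width, out), bn3 = init_bn(out),
    stride = stride
  )
  if (stride != 1L || c_in != out) {
    blk$down_conv <- init_conv(1L, c_in, out)
    blk$down_bn <- init_bn(out)
  }
  blk
}

#' Initialize a residual-network image backbone
#'
#' @param depth 50, 101 or 152 (bottleneck variants; all emit 2048 features).
#' @return nested parameter list with stages `stem`, `layer1`..`layer4`.
#' @export
resnet_init <- function(depth = 101L) {
  blocks <- resnet_stage_blocks(depth)
  widths <- c(64L, 128L, 256L, 512L)
  net <- list(stem = c(init_conv(7L, 3L, 64L), init_bn(64L)))
  c_in <- 64L
  for (s in 1:4) {
    stage <- list()
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      stage[[b]] <- init_bottleneck(c_in, widths[s], stride)
      c_in <- widths[s] * 4L
    }
    net[[paste0("layer", s)]] <- stage
  }
  net$depth <- depth
  net
}

forward_bottleneck <- function(tape, x, blk, H, W) {
  h <- ad_conv2d(tape, x, blk$conv1$W, blk$conv1$b, H, W, 1L, 1L, 0L)
  h <- ad_relu(tape, ad_channel_affine(tape, h, blk$bn1$gamma, blk$bn1$beta))
  h <- ad_conv2d(tape, h, blk$conv2$W, blk$conv2$b, H, W, 3L, blk$stride, 1L)
  H2 <- attr(h, "H"); W2 <- attr(h, "W")
  h <- ad_relu(tape, ad_channel_affine(tape, h, blk$bn2$gamma, blk$bn2$beta))
  h <- ad_conv2d(tape, h, blk$conv3$W, blk$conv3$b, H2, W2, 1L, 1L, 0L)
  h <- ad_channel_affine(tape, h, blk$bn3$gamma, blk$bn3$beta)
  shortcut <- if (!is.null(blk$down_conv)) {
    s <- ad_conv2d(tape, x, blk$down_conv$W, blk$down_conv$b, H, W, 1L, blk$stride, 0L)
    ad_channel_affine(tape, s, blk$down_bn$gamma, blk$down_bn$beta)
  } else x
  out <- ad_relu(tape, ad_axpy(tape, h, shortcut))
  attr(out, "H") <- H2
  attr(out, "W") <- W2
  out
}

# Forward pass from a (H*W) x 3 pixel matrix to the 2048-vector node.
forward_resnet <- function(tape, x, net, H, W) {
  h <- ad_conv2d(tape, x, net$stem$W, net$stem$b, H, W, 7L, 2L, 3L)
  H <- attr(h, "H"); W <- attr(h, "W")
  h <- ad_relu(tape, ad_channel_affine(tape, h, net$stem$gamma, net$stem$beta))
  h <- ad_maxpool(tape, h, H, W, 3L, 2L, 1L)
  H <- attr(h, "H"); W <- attr(h, "W")
  for (s in 1:4) {
    for (blk in net[[paste0("layer", s)]]) {
      h <- forward_bottleneck(tape, h, blk, H, W)
      H <- attr(h, "H"); W <- attr(h, "W")
    }
  }
  ad_mean_rows(tape, h)   # global average pooling -> 1 x 2048
}
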