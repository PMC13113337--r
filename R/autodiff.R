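# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A forward pass records operation nodes on a tape; `ad_backward()` walks the
# tape in reverse and accumulates gradients into every tracked node it reaches.
# Trainable parameters are tracked nodes that live *off* the tape, so their
# gradients survive until the optimizer consumes them.  This is deliberately
# small: exactly the operations the encoders and the fusion transformer need,
# nothing more.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e
}

ad_node <- function(tape, val, parents = list(), backward = NULL, track = TRUE) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$track <- track
  class(n) <- "ad_node"
  if (!is.null(tape)) {
    if (tape$n == length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- n
  }
  n
}

#' Create a trainable parameter node
#' @noRd
ad_param <- function(val) {
  ad_node(NULL, as.matrix(val), track = TRUE)
}

ad_const <- function(val) {
  ad_node(NULL, as.matrix(val), track = FALSE)
}

is_ad_node <- function(x) inherits(x, "ad_node")

ad_operand <- function(x) if (is_ad_node(x)) x else ad_const(x)

ad_value <- function(x) if (is_ad_node(x)) x$val else x

#' Reverse pass: accumulate gradients of `loss` (1x1 node) into tracked nodes
#' @noRd
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!isTRUE(p$track)) next
      g <- gs[[k]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# ---- operations ------------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  a <- ad_operand(a); b <- ad_operand(b)
  ad_node(tape, a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), crossprod(a$val, g))
  })
}

# a %*% t(b)
ad_matmul_t <- function(tape, a, b) {
  a <- ad_operand(a); b <- ad_operand(b)
  ad_node(tape, tcrossprod(a$val, b$val), list(a, b), function(g) {
    list(g %*% b$val, crossprod(g, a$val))
  })
}

# Elementwise add; `b` may be a 1 x d row vector broadcast over the rows of `a`.
ad_add <- function(tape, a, b) {
  a <- ad_operand(a); b <- ad_operand(b)
  broadcast <- nrow(b$val) == 1L && nrow(a$val) > 1L
  val <- if (broadcast) sweep(a$val, 2L, b$val[1L, ], "+") else a$val + b$val
  ad_node(tape, val, list(a, b), function(g) {
    gb <- if (broadcast) matrix(colSums(g), 1L) else g
    list(g, gb)
  })
}

# a + k * b for matrices of identical shape (k a plain scalar)
ad_axpy <- function(tape, a, b, k = 1) {
  a <- ad_operand(a); b <- ad_operand(b)
  ad_node(tape, a$val + k * b$val, list(a, b), function(g) list(g, k * g))
}

ad_scale <- function(tape, a, k) {
  a <- ad_operand(a)
  ad_node(tape, k * a$val, list(a), function(g) list(k * g))
}

ad_relu <- function(tape, a) {
  a <- ad_operand(a)
  keep <- a$val > 0
  ad_node(tape, a$val * keep, list(a), function(g) list(g * keep))
}

ad_dropout <- function(tape, a, p) {
  a <- ad_operand(a)
  if (p <= 0) return(a)
  mask <- matrix((stats::runif(length(a$val)) >= p) / (1 - p),
                 nrow(a$val), ncol(a$val))
  ad_node(tape, a$val * mask, list(a), function(g) list(g * mask))
}

ad_softmax_rows <- function(tape, a) {
  a <- ad_operand(a)
  z <- a$val - apply(a$val, 1L, max)
  e <- exp(z)
  y <- e / rowSums(e)
  ad_node(tape, y, list(a), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

# Row-wise layer normalization with learnable 1 x d scale/shift.
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  x <- ad_operand(x); gamma <- ad_operand(gamma); beta <- ad_operand(beta)
  n <- nrow(x$val); d <- ncol(x$val)
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  gmat <- matrix(gamma$val[1L, ], n, d, byrow = TRUE)
  val <- xhat * gmat + matrix(beta$val[1L, ], n, d, byrow = TRUE)
  ad_node(tape, val, list(x, gamma, beta), function(g) {
    dxhat <- g * gmat
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

# Mean over rows -> 1 x d
ad_mean_rows <- function(tape, x) {
  x <- ad_operand(x)
  n <- nrow(x$val)
  ad_node(tape, matrix(colMeans(x$val), 1L), list(x), function(g) {
    list(matrix(g[1L, ], n, ncol(g), byrow = TRUE) / n)
  })
}

ad_rbind <- function(tape, xs) {
  xs <- lapply(xs, ad_operand)
  rows <- vapply(xs, function(x) nrow(x$val), integer(1))
  ad_node(tape, do.call(rbind, lapply(xs, function(x) x$val)), xs, function(g) {
    hi <- cumsum(rows); lo <- hi - rows + 1L
    lapply(seq_along(xs), function(k) g[lo[k]:hi[k], , drop = FALSE])
  })
}

ad_cbind <- function(tape, xs) {
  xs <- lapply(xs, ad_operand)
  cols <- vapply(xs, function(x) ncol(x$val), integer(1))
  ad_node(tape, do.call(cbind, lapply(xs, function(x) x$val)), xs, function(g) {
    hi <- cumsum(cols); lo <- hi - cols + 1L
    lapply(seq_along(xs), function(k) g[, lo[k]:hi[k], drop = FALSE])
  })
}

ad_cols <- function(tape, x, idx) {
  x <- ad_operand(x)
  dims <- dim(x$val)
  ad_node(tape, x$val[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, dims[1L], dims[2L])
    gx[, idx] <- g
    list(gx)
  })
}

# Mean squared error over all entries; target is a constant.
ad_mse <- function(tape, pred, target) {
  pred <- ad_operand(pred)
  tgt <- ad_value(target)
  diff <- pred$val - tgt
  ad_node(tape, matrix(mean(diff^2), 1L, 1L), list(pred), function(g) {
    list(2 * diff / length(diff) * g[1L, 1L])
  })
}

# Row-wise sum of squared errors, averaged over rows (squared L2 per sample).
ad_mse_rows <- function(tape, pred, target) {
  pred <- ad_operand(pred)
  tgt <- ad_value(target)
  diff <- pred$val - tgt
  m <- nrow(diff)
  ad_node(tape, matrix(sum(diff^2) / m, 1L, 1L), list(pred), function(g) {
    list(2 * diff / m * g[1L, 1L])
  })
}

# Label-smoothing cross entropy: -mean_m sum_c soft[m,c] * log softmax(logits)[m,c]
ad_lsce <- function(tape, logits, soft_targets) {
  logits <- ad_operand(logits)
  tgt <- ad_value(soft_targets)
  z <- logits$val - apply(logits$val, 1L, max)
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  m <- nrow(logp)
  val <- -sum(tgt * logp) / m
  p <- exp(logp)
  ad_node(tape, matrix(val, 1L, 1L), list(logits), function(g) {
    list((p * rowSums(tgt) - tgt) / m * g[1L, 1L])
  })
}

# ---- optimizer -------------------------------------------------------------

#' Adam optimizer over a flat list of parameter nodes
#'
#' Classic Adam with L2 weight decay folded into the gradient (the convention
#' of mainstream deep-learning frameworks when `weight_decay` is passed to
#' Adam, as opposed to decoupled AdamW).
#' @noRd
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay
  st$t <- 0L
  st$m <- lapply(params, function(p) p$val * 0)
  st$v <- lapply(params, function(p) p$val * 0)
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (k in seq_along(opt$params)) {
    p <- opt$params[[k]]
    g <- p$grad
    if (is.null(g)) next
    if (opt$wd > 0) g <- g + opt$wd * p$val
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g^2
    p$val <- p$val - opt$lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + opt$eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Collect every ad_param in a (possibly nested) list structure, named by path.
collect_params <- function(x, prefix = "") {
  if (is_ad_node(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nm <- names(x) %||% as.character(seq_along(x))
    for (k in seq_along(x)) {
      sub <- collect_params(x[[k]], paste0(prefix, if (nzchar(prefix)) "." else "", nm[k]))
      out <- c(out, sub)
    }
    return(out)
  }
  list()
}
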