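#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators never
#' perturb the global RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

abort_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort_input(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

# Rolling (centered, truncated) window sums via cumulative sums.  For sample i
# the window covers indices max(1, i - floor(w/2)) .. min(n, i + ceiling(w/2) - 1).
rolling_window_bounds <- function(n, w) {
  half_lo <- floor(w / 2)
  lo <- pmax(1L, seq_len(n) - half_lo)
  hi <- pmin(n, seq_len(n) + (ceiling(w / 2) - 1L))
  list(lo = lo, hi = hi, size = hi - lo + 1L)
}

rolling_mean_sd <- function(x, w) {
  n <- length(x)
  b <- rolling_window_bounds(n, w)
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  s1 <- c1[b$hi + 1L] - c1[b$lo]
  s2 <- c2[b$hi + 1L] - c2[b$lo]
  m <- s1 / b$size
  # sample variance (n-1); windows of size 1 get sd 0
  v <- ifelse(b$size > 1L, pmax(0, (s2 - s1^2 / b$size) / (b$size - 1L)), 0)
  list(mean = m, sd = sqrt(v), size = b$size)
}

rolling_mean <- function(x, w) {
  n <- length(x)
  b <- rolling_window_bounds(n, w)
  c1 <- c(0, cumsum(x))
  (c1[b$hi + 1L] - c1[b$lo]) / b$size
}

# Linear 1-D interpolation weights used by bilinear resizing (align-corners
# convention: first/last input samples map onto first/last output samples, so
# resizing to the same size is the identity).
resize_positions <- function(n_in, n_out) {
  if (n_in == 1L) return(list(lo = rep(1L, n_out), hi = rep(1L, n_out), w = rep(0, n_out)))
  pos <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 1L)
  list(lo = as.integer(lo), hi = as.integer(lo) + 1L, w = pos - lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
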