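# Gramian Angular Difference Field imaging of FHR series.
#
# A series is min-max rescaled into [a,b] within [-1,1], mapped to polar
# angles phi = arccos(x), and paired into a Gramian matrix.  The default
# variant is the cosine form G[i,j] = cos(phi_i - phi_j) (symmetric, unit
# diagonal); the classical antisymmetric sine form sin(phi_i - phi_j) is
# available via `variant = "sin"`.  The matrix is bilinearly resized to a
# fixed resolution (default 224 x 224) for the image encoder.

#' GADF configuration
#'
#' @param range_low,range_high rescaling interval `[a, b]` with
#'   `-1 <= a < b <= 1`.
#' @param out_size output image side length in pixels.
#' @param fast_path when `TRUE`, the series is piecewise-aggregate downsampled
#'   to `out_size` points before the transform and no resize is performed
#'   (approximate but much cheaper for long series).
#' @param variant `"cos"` for `cos(phi_i - phi_j)` (default) or `"sin"` for
#'   the classical antisymmetric difference field.
#' @export
gadf_config <- function(range_low = -1, range_high = 1, out_size = 224L,
                        fast_path = FALSE, variant = c("cos", "sin")) {
  variant <- match.arg(variant)
  if (!(range_low >= -1 && range_low < range_high && range_high <= 1)) {
    abort_input("require -1 <= range_low < range_high <= 1")
  }
  if (out_size < 2) abort_input("out_size must be >= 2")
  structure(list(range_low = range_low, range_high = range_high,
                 out_size = as.integer(out_size), fast_path = fast_path,
                 variant = variant),
            class = "gadf_config")
}

#' Min-max rescale a series into `[a, b]`
#'
#' The minimum maps to `a` and the maximum to `b`.  A constant series maps
#' every sample to the interval midpoint `(a+b)/2`, so fully flat (fully
#' interpolated) segments still produce an image.
#'
#' @param x numeric vector.
#' @param config a [gadf_config()].
#' @export
gadf_rescale <- function(x, config = gadf_config()) {
  if (length(x) == 0L) abort_input("empty series")
  a <- config$range_low; b <- config$range_high
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep((a + b) / 2, length(x)))
  pmin(pmax(a + (b - a) * (x - rng[1]) / (rng[2] - rng[1]), a), b)
}

#' Map a normalized series to polar angles
#'
#' `phi = arccos(x)` in `[0, pi]`, monotone decreasing in `x`.  Tiny numeric
#' overshoot of `[-1, 1]` (up to `tol`) is clamped; anything larger is a
#' domain error.
#'
#' @param x normalized series in `[-1, 1]`.
#' @param tol clamping tolerance.
#' @export
to_polar <- function(x, tol = 1e-8) {
  if (any(x < -1 - tol | x > 1 + tol)) {
    abort_input("values outside [-1, 1]: rescale the series first")
  }
  acos(pmin(pmax(x, -1), 1))
}

#' Gramian angular matrix from a polar-angle sequence
#'
#' `variant = "cos"` gives `G[i,j] = cos(phi_i - phi_j)` (symmetric with unit
#' diagonal); `variant = "sin"` gives `sin(phi_i - phi_j)` (antisymmetric with
#' zero diagonal).  Both expand to rank-2 outer products of `cos(phi)` and
#' `sin(phi)`, which is how they are computed.
#'
#' @param phi angle sequence in radians.
#' @param variant `"cos"` or `"sin"`.
#' @export
gadf_matrix <- function(phi, variant = c("cos", "sin")) {
  variant <- match.arg(variant)
  if (length(phi) == 0L) abort_input("empty angle sequence")
  cp <- cos(phi); sp <- sin(phi)
  G <- if (variant == "cos") {
    # cos(phi_i - phi_j) = cos(phi_i)cos(phi_j) + sin(phi_i)sin(phi_j)
    tcrossprod(cp) + tcrossprod(sp)
  } else {
    # sin(phi_i - phi_j) = sin(phi_i)cos(phi_j) - cos(phi_i)sin(phi_j)
    tcrossprod(sp, cp) - tcrossprod(cp, sp)
  }
  # guard sub-ulp overshoot of the analytic [-1, 1] range
  pmin(pmax(G, -1), 1)
}

# 1-D linear interpolation matrix rows applied to a vector (align-corners)
interp_vector <- function(v, n_out) {
  p <- resize_positions(length(v), n_out)
  v[p$lo] * (1 - p$w) + v[p$hi] * p$w
}

#' Bilinearly resize a square matrix
#'
#' Separable bilinear interpolation with the align-corners convention, so
#' resizing to the input size is the identity and every output pixel is a
#' convex combination of input pixels (output range within input range).
#'
#' @param G square numeric matrix.
#' @param out_size output side length.
#' @export
bilinear_resize <- function(G, out_size) {
  n <- nrow(G)
  if (n != ncol(G)) abort_input("matrix must be square")
  if (n == out_size) return(G)
  p <- resize_positions(n, out_size)
  rows <- G[p$lo, , drop = FALSE] * (1 - p$w) + G[p$hi, , drop = FALSE] * p$w
  rows[, p$lo, drop = FALSE] * matrix(1 - p$w, out_size, out_size, byrow = TRUE) +
    rows[, p$hi, drop = FALSE] * matrix(p$w, out_size, out_size, byrow = TRUE)
}

#' Render a Gramian matrix as a fixed-size image
#'
#' @param G square matrix with entries in `[-1, 1]`.
#' @param config a [gadf_config()].
#' @return a `gadf_image`: list with `pixels` (`out_size` x `out_size` matrix
#'   in `[-1, 1]`), `size` and `source_length`.
#' @export
gadf_render <- function(G, config = gadf_config()) {
  px <- bilinear_resize(G, config$out_size)
  structure(list(pixels = px, size = config$out_size, source_length = nrow(G)),
            class = "gadf_image")
}

# Piecewise aggregate approximation: mean over out_size near-equal bins.
paa_downsample <- function(x, n_out) {
  n <- length(x)
  if (n <= n_out) return(x)
  bin <- floor(seq(0, n_out, length.out = n + 1)[-1] - 1e-9) + 1
  as.numeric(rowsum(x, bin) / tabulate(bin, n_out))
}

#' Transform a preprocessed FHR series into a GADF image
#'
#' The faithful path composes rescale -> polar -> Gramian matrix -> bilinear
#' resize.  Because the Gramian is a rank-2 combination of `cos(phi)` and
#' `sin(phi)` and bilinear resizing is separable and linear, for long series
#' the resized image is computed exactly (to rounding) by interpolating the
#' two vectors first, avoiding the L x L intermediate; this is an algebraic
#' identity, not an approximation.  With `fast_path = TRUE` the series is
#' piecewise-aggregate downsampled to `out_size` points first and no resize is
#' performed (approximate).
#'
#' @param fhr preprocessed (finite) FHR series.
#' @param config a [gadf_config()].
#' @return a `gadf_image`.
#' @export
fhr_to_gadf <- function(fhr, config = gadf_config()) {
  if (any(!is.finite(fhr))) abort_input("fhr must be finite: preprocess first")
  L <- length(fhr)
  if (config$fast_path && L > config$out_size) {
    x <- paa_downsample(fhr, config$out_size)
    phi <- to_polar(gadf_rescale(x, config))
    G <- gadf_matrix(phi, config$variant)
    return(structure(list(pixels = G, size = nrow(G), source_length = L),
                     class = "gadf_image"))
  }
  phi <- to_polar(gadf_rescale(fhr, config))
  if (L > 1024L && L != config$out_size) {
    # separable shortcut: interpolate cos/sin then form the outer products
    cp <- interp_vector(cos(phi), config$out_size)
    sp <- interp_vector(sin(phi), config$out_size)
    G <- if (config$variant == "cos") tcrossprod(cp) + tcrossprod(sp)
         else tcrossprod(sp, cp) - tcrossprod(cp, sp)
    G <- pmin(pmax(G, -1), 1)
    return(structure(list(pixels = G, size = config$out_size, source_length = L),
                     class = "gadf_image"))
  }
  gadf_render(gadf_matrix(phi, config$variant), config)
}

#' Export a GADF image to a plain-text portable graymap (PGM, P2)
#'
#' Applies the affine `[-1, 1] -> [0, 255]` mapping.  For visual inspection
#' only; the model consumes the float matrix.
#'
#' @param image a `gadf_image`.
#' @param path output file path.
#' @export
write_gadf_pgm <- function(image, path) {
  px <- round((image$pixels + 1) / 2 * 255)
  px <- pmin(pmax(px, 0), 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(image$size, image$size), "255"), con)
  utils::write.table(px, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.gadf_image <- function(x, ...) {
  cat(sprintf("<gadf_image> %dx%d from series of length %d, range [%.3f, %.3f]\n",
              x$size, x$size, x$source_length, min(x$pixels), max(x$pixels)))
  invisible(x)
}
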