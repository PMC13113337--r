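test_that("rescaling maps extremes to the interval ends and constants to the midpoint", {
  cfg <- gadf_config()
  expect_equal(gadf_rescale(c(100, 150, 200), cfg), c(-1, 0, 1))
  expect_equal(gadf_rescale(c(130, 130, 130), cfg), c(0, 0, 0))
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(50)
    y <- gadf_rescale(x, gadf_config(range_low = -0.8, range_high = 0.5))
    expect_equal(min(y), -0.8)
    expect_equal(max(y), 0.5)
  }
  expect_error(gadf_config(range_low = 0.5, range_high = 0.5), "range_low")
})

test_that("polar mapping hits the documented endpoints and rejects bad domains", {
  expect_equal(to_polar(1), 0)
  expect_equal(to_polar(0), pi / 2)
  expect_equal(to_polar(-1), pi)
  expect_equal(to_polar(1 + 1e-12), 0)        # tiny overshoot clamped
  expect_error(to_polar(1.5), "outside")
  x <- seq(-1, 1, length.out = 21)
  expect_true(all(diff(to_polar(x)) < 0))     # monotone decreasing
})

test_that("gadf_matrix equals the brute-force double loop for both variants", {
  expect_equal(gadf_matrix(c(0, pi)), rbind(c(1, -1), c(-1, 1)))
  set.seed(11)
  phi <- runif(50, 0, pi)
  G <- gadf_matrix(phi)
  brute <- outer(seq_along(phi), seq_along(phi),
                 Vectorize(function(i, j) cos(phi[i] - phi[j])))
  expect_equal(G, brute)
  expect_equal(diag(G), rep(1, 50))
  expect_equal(G, t(G))
  Gs <- gadf_matrix(phi, variant = "sin")
  brute_s <- outer(seq_along(phi), seq_along(phi),
                   Vectorize(function(i, j) sin(phi[i] - phi[j])))
  expect_equal(Gs, brute_s)
  expect_equal(Gs, -t(Gs))
  expect_equal(diag(Gs), rep(0, 50))
})

test_that("bilinear resize is the identity at equal size and convex otherwise", {
  set.seed(4)
  G <- matrix(runif(224 * 224, -1, 1), 224)
  img <- gadf_render(G, gadf_config())
  expect_identical(img$pixels, G)

  expect_equal(gadf_render(matrix(0.4, 10, 10), gadf_config(out_size = 32))$pixels,
               matrix(0.4, 32, 32))
  G <- matrix(runif(50 * 50, -0.7, 0.9), 50)
  out <- bilinear_resize(G, 224)
  expect_gte(min(out), min(G))
  expect_lte(max(out), max(G))
})

test_that("fhr_to_gadf composes the pipeline and keeps pixels in [-1, 1]", {
  # identity case: a length-224 ramp needs no resize and no aggregation
  ramp <- seq(100, 180, length.out = 224)
  cfg <- gadf_config()
  faithful <- fhr_to_gadf(ramp, cfg)
  fast <- fhr_to_gadf(ramp, gadf_config(fast_path = TRUE))
  expect_equal(faithful$pixels, fast$pixels)
  expect_true(all(faithful$pixels >= -1 & faithful$pixels <= 1))

  # the separable rank-2 shortcut is an exact identity with the composition
  set.seed(8)
  x <- rnorm(300, 140, 10)
  via_shortcut <- fhr_to_gadf(c(x, rnorm(1200, 140, 10)), gadf_config(out_size = 64))
  expect_equal(via_shortcut$size, 64L)
  long <- rnorm(1500, 140, 10)
  phi <- to_polar(gadf_rescale(long, gadf_config(out_size = 64)))
  composed <- gadf_render(gadf_matrix(phi), gadf_config(out_size = 64))
  expect_equal(fhr_to_gadf(long, gadf_config(out_size = 64))$pixels,
               composed$pixels, tolerance = 1e-12)
  expect_error(fhr_to_gadf(c(1, NA, 3)), "finite")
})

test_that("fast path tracks the faithful path on a slow smooth series", {
  # regression tolerance frozen from the first computation (0.075 measured)
  x <- 140 + 20 * sin(2 * pi * (0:7199) / 3600)
  d <- max(abs(fhr_to_gadf(x, gadf_config())$pixels -
               fhr_to_gadf(x, gadf_config(fast_path = TRUE))$pixels))
  expect_lt(d, 0.1)
})

test_that("time reversal permutes the Gramian by index reversal", {
  set.seed(15)
  x <- rnorm(40, 140, 8)
  phi <- to_polar(gadf_rescale(x, gadf_config()))
  phir <- to_polar(gadf_rescale(rev(x), gadf_config()))
  G <- gadf_matrix(phi)
  Gr <- gadf_matrix(phir)
  n <- length(x)
  expect_equal(Gr, G[n:1, n:1])
})

test_that("GADF texture differs between classes on strongly decelerating fixtures", {
  # On this generator the *normal* class shows the higher fine-scale contrast:
  # min-max rescaling lets deep decelerations compress the variability band.
  # The classes remain clearly separated by the statistic either way.
  ds <- generate_dataset(synthetic_config(n_records = 10, abnormal_fraction = 0.5,
                                          seed = 5, segment_length = 1200,
                                          contraction_period = 90, decel_depth = 40))
  labs <- vapply(ds, `[[`, integer(1), "label")
  contrast <- vapply(ds, function(r) {
    px <- fhr_to_gadf(preprocess_record(r)$record$fhr,
                      gadf_config(out_size = 64, fast_path = TRUE))$pixels
    mean(abs(diff(px))) + mean(abs(t(diff(t(px)))))
  }, numeric(1))
  expect_gt(abs(mean(contrast[labs == 0]) - mean(contrast[labs == 1])),
            2 * max(stats::sd(contrast[labs == 0]), stats::sd(contrast[labs == 1])) / sqrt(5))
  expect_gt(mean(contrast[labs == 0]), mean(contrast[labs == 1]))
})

test_that("PGM export is plain text with an 8-bit affine mapping", {
  img <- fhr_to_gadf(seq(110, 160, length.out = 64), gadf_config(out_size = 32))
  path <- withr::local_tempfile(fileext = ".pgm")
  write_gadf_pgm(img, path)
  lines <- readLines(path)
  expect_identical(lines[1], "P2")
  expect_identical(lines[2], "32 32")
  vals <- scan(text = paste(lines[-(1:3)], collapse = " "), quiet = TRUE)
  expect_true(all(vals >= 0 & vals <= 255))
})
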