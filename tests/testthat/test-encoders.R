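test_that("instance normalization matches the population-sd convention", {
  expect_equal(instance_normalize(c(1, 2, 3)), c(-1.2247, 0, 1.2247),
               tolerance = 1e-3)
  expect_equal(instance_normalize(rep(42, 10)), rep(0, 10))
  set.seed(1)
  x <- rnorm(100, 140, 9)
  expect_equal(instance_normalize(3 * x + 17), instance_normalize(x),
               tolerance = 1e-4)
  # idempotent up to the eps guard
  expect_equal(instance_normalize(instance_normalize(x)), instance_normalize(x),
               tolerance = 1e-4)
})

test_that("patch counts agree with a sliding-window enumerator", {
  enumerate <- function(L, P, S) {
    n <- 0L; start <- 1L
    repeat {
      n <- n + 1L
      if (start + P - 1L >= L) break   # this patch (zero-padded) reaches the end
      start <- start + S
    }
    n
  }
  expect_equal(patch_count(7200, 64, 32), 224L)
  set.seed(7)
  for (i in 1:30) {
    L <- sample(50:500, 1)
    P <- sample(4:min(64, L), 1)
    S <- sample(seq_len(P), 1)
    expect_equal(patch_count(L, P, S), enumerate(L, P, S),
                 info = sprintf("L=%d P=%d S=%d", L, P, S))
  }
  expect_error(patch_count(10, 20, 5), "exceeds")
})

test_that("patchify lays out offsets and zero padding as documented", {
  p <- patchify(1:8, 4, 2)
  expect_equal(dim(p), c(3L, 4L))
  expect_equal(p[1, ], 1:4)
  expect_equal(p[2, ], 3:6)
  expect_equal(p[3, ], 5:8)
  p <- patchify(1:9, 4, 2)
  expect_equal(nrow(p), 4L)
  expect_equal(p[4, ], c(7, 8, 9, 0))
})

test_that("the CTG encoder honours its architecture contract", {
  cfg <- ctg_encoder_config(patch_length = 16, stride = 8, d_model = 16,
                            n_layers = 1, n_heads = 2, ffn_width = 32)
  set.seed(2)
  w <- ctg_encoder_init(cfg, 128L)
  fhr <- rnorm(128, 140, 8); uc <- rnorm(128, 20, 5)
  g <- encode_ctg(fhr, uc, cfg, w)
  expect_length(g, 2L * cfg$d_model)
  # channel independence: perturbing UC leaves the FHR half unchanged
  g2 <- encode_ctg(fhr, uc + rnorm(128), cfg, w)
  expect_identical(g[1:16], g2[1:16])
  expect_false(identical(g[17:32], g2[17:32]))
  # weight sharing: identical channels produce identical halves
  g3 <- encode_ctg(fhr, fhr, cfg, w)
  expect_equal(g3[1:16], g3[17:32])
  expect_error(encode_ctg(fhr, uc[-1], cfg, w), "equal length")
  # FHR-only ablation halves the output width
  cfg1 <- ctg_encoder_config(patch_length = 16, stride = 8, d_model = 16,
                             n_layers = 1, n_heads = 2, ffn_width = 32,
                             channels = "fhr")
  set.seed(2)
  w1 <- ctg_encoder_init(cfg1, 128L)
  expect_length(encode_ctg(fhr, NULL, cfg1, w1), 16L)
})

test_that("metadata statistics use the sample-sd convention and guard zero variance", {
  recs <- lapply(c(20, 30, 40), function(a) {
    ctg_record(paste0("r", a), 1:4, 1:4,
               maternal_metadata(a, a / 10 - 1, a / 10 - 2, 0), 0)
  })
  st <- fit_metadata_stats(recs)
  expect_equal(unname(st$mean[["age"]]), 30)
  expect_equal(unname(st$sd[["age"]]), 10)          # sample sd
  expect_warning(fit_metadata_stats(recs[c(1, 1)]), "zero-variance")
  # a missing gravidity is excluded from the mean that later imputes it
  recs[[2]]$metadata$gravidity <- NA
  st2 <- suppressWarnings(fit_metadata_stats(recs))
  expect_equal(unname(st2$mean[["gravidity"]]), 2)
  expect_error(fit_metadata_stats(recs[1]), "at least 2")
})

test_that("standardization z-scores, imputes and passes diabetes through", {
  recs <- lapply(1:4, function(i) {
    ctg_record(paste0("r", i), 1:4, 1:4,
               maternal_metadata(24 + 2 * i, i, i - 1, i %% 2), 0)
  })
  st <- fit_metadata_stats(recs)
  v <- standardize_metadata(maternal_metadata(mean(26 + 2 * (0:3)) , 2, 1, 1), st)
  expect_equal(v[1], 0)                      # age at the training mean
  expect_equal(v[4], 1)                      # diabetes untouched
  v2 <- standardize_metadata(maternal_metadata(30, NA, 1, 0), st)
  expect_equal(v2[2], 0)                     # imputed then z-scored to 0
})

test_that("the metadata autoencoder has the stated shapes and trains to low error", {
  cfg <- metadata_encoder_config()
  set.seed(3)
  w <- metadata_ae_init(cfg)
  z <- encode_metadata(c(0.5, -1, 0.2, 1), w)
  expect_length(z, 32L)
  expect_length(decode_metadata(z, w), 4L)
  for (p in ctgfuse:::collect_params(w)) p$val[] <- 0
  expect_equal(encode_metadata(c(1, 1, 1, 1), w), rep(0, 32))
  expect_equal(decode_metadata(rep(1, 32), w), rep(0, 4))

  # trained alone on 16 fixed vectors the reconstruction MSE drops below 0.05
  set.seed(3)
  w <- metadata_ae_init(cfg)
  X <- matrix(rnorm(64), 16, 4); X[, 4] <- rbinom(16, 1, 0.5)
  ps <- ctgfuse:::collect_params(w)
  opt <- ctgfuse:::adam_new(ps, lr = 1e-2)
  for (it in 1:300) {
    tape <- ctgfuse:::ad_tape()
    zt <- ctgfuse:::forward_metadata_enc(tape, ctgfuse:::ad_const(X), w)
    xh <- ctgfuse:::forward_metadata_dec(tape, zt, w)
    loss <- ctgfuse:::ad_mse(tape, xh, X)
    ctgfuse:::zero_grads(ps)
    ctgfuse:::ad_backward(tape, loss)
    ctgfuse:::adam_step(opt)
  }
  expect_lt(loss$val[1, 1], 0.05)
})

test_that("the tiny image backbone is deterministic with the configured width", {
  cfg <- image_encoder_config(backbone = "tiny", input_size = 16,
                              tiny_hidden = 8, tiny_out = 12)
  set.seed(5)
  w <- image_encoder_init(cfg)
  img <- make_gadf_image(matrix(runif(256, -1, 1), 16))
  f <- encode_image(img, cfg, w)
  expect_length(f, 12L)
  expect_identical(f, encode_image(img, cfg, w))
  expect_error(encode_image(make_gadf_image(matrix(0, 8, 8)), cfg, w), "16x16")
})
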