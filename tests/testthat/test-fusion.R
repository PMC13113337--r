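test_that("label smoothing follows the soft-target formula", {
  expect_equal(smooth_labels(1, 0.1, 2), c(0.1, 0.9))
  expect_equal(smooth_labels(0, 0, 2), c(1, 0))
  for (eps in c(0, 0.1, 0.3)) {
    expect_equal(sum(smooth_labels(1, eps, 4)), 1)
  }
  expect_error(smooth_labels(2, 0.1, 2), "class label")
  expect_error(loss_config(smoothing = 1), "smoothing")
})

test_that("the composite loss combines its components as stated", {
  # uniform prediction gives ln 2 for any smoothing (soft labels sum to 1)
  for (eps in c(0, 0.1, 0.3)) {
    l <- composite_loss(matrix(c(0, 0), 1), 1, config = loss_config(smoothing = eps))
    expect_equal(l$cls, log(2))
  }
  # perfect reconstruction contributes nothing
  l <- composite_loss(matrix(c(0, 3), 1), 1, recon = matrix(1:4, 1),
                      targets = matrix(1:4, 1))
  expect_equal(l$rec, 0)
  expect_equal(l$total, l$cls)
  # plain arithmetic of L = Lcls + lambda * Lrec on fixed components
  l <- composite_loss(matrix(c(0, 0), 1), 0, recon = matrix(0, 1, 1),
                      targets = matrix(sqrt(0.2), 1, 1),
                      config = loss_config(recon_weight = 0.5))
  expect_equal(l$total, l$cls + 0.5 * 0.2)
})

test_that("LSCE is minimized where the prediction equals the soft target", {
  soft <- smooth_labels(1, 0.1, 2)
  obj <- function(lg) composite_loss(matrix(lg, 1), 1,
                                     config = loss_config(smoothing = 0.1))$cls
  opt <- optim(c(0, 0), obj)
  p <- exp(opt$par - max(opt$par)); p <- p / sum(p)
  expect_equal(p, soft, tolerance = 1e-3)
})

test_that("the classification head behaves like a two-logit softmax", {
  set.seed(41)
  w <- list(classifier = ctgfuse:::init_linear(8, 2))
  out <- classify(rnorm(8), w)
  expect_length(out$logits, 2L)
  expect_gte(out$probability, 0)
  expect_lte(out$probability, 1)
  # equal logits give probability one half
  w$classifier$W$val[] <- 0; w$classifier$b$val[] <- 0
  expect_equal(classify(rnorm(8), w)$probability, 0.5)
  # increasing the abnormal logit strictly increases the probability
  w$classifier$b$val[1, ] <- c(0, 0.5)
  p1 <- classify(rep(0, 8), w)$probability
  w$classifier$b$val[1, ] <- c(0, 1.5)
  expect_gt(classify(rep(0, 8), w)$probability, p1)
})

test_that("token projection is shaped, ordered and row-independent", {
  set.seed(42)
  w <- list(proj_signal = ctgfuse:::init_linear(6, 4),
            proj_image = ctgfuse:::init_linear(5, 4),
            proj_metadata = ctgfuse:::init_linear(3, 4))
  g <- rnorm(6); f <- rnorm(5); z <- rnorm(3)
  X <- project_tokens(g, f, z, w)
  expect_equal(dim(X), c(3L, 4L))
  X2 <- project_tokens(g, rnorm(5), z, w)
  expect_identical(X[c(1, 3), ], X2[c(1, 3), ])
  expect_false(identical(X[2, ], X2[2, ]))
  for (p in ctgfuse:::collect_params(w)) p$val[] <- 0
  expect_equal(project_tokens(g, f, z, w), matrix(0, 3, 4))
  expect_error(project_tokens(rnorm(2), f, z, w), "dimension mismatch")
})

test_that("zeroed attention and feed-forward reduce fusion to stacked LayerNorms", {
  set.seed(43)
  d <- 4L
  cfg <- fusion_config(d_common = d, n_layers = 1, n_heads = 2, ffn_width = 8)
  w <- list(modality_emb = ctgfuse:::ad_param(matrix(0, 3, d)),
            blocks = ctgfuse:::init_encoder_stack(1, d, 8))
  blk <- w$blocks[[1]]
  blk$mhsa$o$W$val[] <- 0; blk$mhsa$o$b$val[] <- 0
  blk$ffn$fc2$W$val[] <- 0; blk$ffn$fc2$b$val[] <- 0
  X0 <- matrix(rnorm(3 * d), 3, d)
  ln <- function(M, eps = 1e-5) {
    t(apply(M, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)))
  }
  expect_equal(fuse(X0, cfg, w), colMeans(ln(ln(X0))), tolerance = 1e-12)
})

test_that("multi-head attention matches a hand-rolled single-example computation", {
  set.seed(44)
  d <- 4L
  pars <- ctgfuse:::init_mhsa(d)
  H <- matrix(rnorm(3 * d), 3, d)
  tape <- ctgfuse:::ad_tape()
  got <- ctgfuse:::forward_mhsa(tape, ctgfuse:::ad_const(H), pars, 1L)$val
  lin <- function(X, l) sweep(X %*% l$W$val, 2, l$b$val[1, ], "+")
  Q <- lin(H, pars$q); K <- lin(H, pars$k); V <- lin(H, pars$v)
  S <- Q %*% t(K) / sqrt(d)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(got, lin(A %*% V, pars$o), tolerance = 1e-12)
  expect_equal(rowSums(A), rep(1, 3))   # softmax rows are normalized
})

test_that("post-norm block algebra matches a plain-matrix reference", {
  set.seed(45)
  d <- 4L
  blk <- ctgfuse:::init_encoder_block(d, 8)
  H <- matrix(rnorm(3 * d), 3, d)
  tape <- ctgfuse:::ad_tape()
  got <- ctgfuse:::forward_encoder_block(tape, ctgfuse:::ad_const(H), blk, 2L)$val
  lin <- function(X, l) sweep(X %*% l$W$val, 2, l$b$val[1, ], "+")
  ln <- function(M, g, b, eps = 1e-5) {
    xh <- t(apply(M, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)))
    sweep(sweep(xh, 2, g$val[1, ], "*"), 2, b$val[1, ], "+")
  }
  mhsa <- function(X, pars, h) {
    dh <- d / h
    heads <- lapply(seq_len(h), function(k) {
      idx <- ((k - 1) * dh + 1):(k * dh)
      Q <- lin(X, pars$q)[, idx, drop = FALSE]
      K <- lin(X, pars$k)[, idx, drop = FALSE]
      V <- lin(X, pars$v)[, idx, drop = FALSE]
      S <- Q %*% t(K) / sqrt(dh)
      A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
      A %*% V
    })
    lin(do.call(cbind, heads), pars$o)
  }
  H1 <- ln(H + mhsa(H, blk$mhsa, 2), blk$ln1$gamma, blk$ln1$beta)
  ffn <- lin(pmax(lin(H1, blk$ffn$fc1), 0), blk$ffn$fc2)
  ref <- ln(H1 + ffn, blk$ln2$gamma, blk$ln2$beta)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("baseline fusion strategies behave as stated", {
  v <- c(1, 2, 3)
  expect_equal(fuse_baseline(list(v, v, v), "add"), 3 * v)
  expect_length(fuse_baseline(list(v, v + 1, v + 2), "concat"), 9L)
  toks <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  expect_equal(fuse_baseline(toks, "add"), fuse_baseline(rev(toks), "add"))
  expect_false(identical(fuse_baseline(toks, "concat"),
                         fuse_baseline(rev(toks), "concat")))
  set.seed(46)
  w <- list(fc1 = ctgfuse:::init_linear(6, 8), fc2 = ctgfuse:::init_linear(8, 2))
  expect_length(fuse_baseline(toks, "mlp", w), 2L)
  expect_error(fuse_baseline(toks, "gated"), "unknown fusion strategy")
})

test_that("every strategy x modality-mask x patch-grid configuration runs finite", {
  ds <- generate_dataset(synthetic_config(
    n_records = 1, abnormal_fraction = 1, seed = 6, segment_length = 512,
    contraction_period = 60))
  masks <- list(c("signal", "image", "metadata"), c("image", "metadata"),
                c("signal", "metadata"), c("signal", "image"))
  grid <- list(c(64, 16), c(64, 32), c(96, 24), c(128, 24), c(128, 32))
  for (strategy in c("transformer", "concat", "add", "mlp")) {
    for (mask in masks) {
      for (ps in grid) {
        mc <- model_config(
          ctg = ctg_encoder_config(patch_length = ps[1], stride = ps[2],
                                   d_model = 16, n_layers = 1, n_heads = 2,
                                   ffn_width = 16, dropout = 0),
          image = image_encoder_config(backbone = "tiny", input_size = 8,
                                       tiny_hidden = 8, tiny_out = 8),
          fusion = fusion_config(d_common = 16, n_layers = 1, n_heads = 2,
                                 ffn_width = 16, strategy = strategy,
                                 modality_mask = mask),
          segment_length = 512L)
        set.seed(47)
        model <- model_init(mc)
        feats <- prepare_features(ds, mc, if ("metadata" %in% mask) {
          suppressWarnings(fit_metadata_stats(rep(ds, 2)))
        } else NULL)
        out <- predict_record(model, feats[[1]])
        expect_true(all(is.finite(out$logits)),
                    info = paste(strategy, paste(mask, collapse = "+"),
                                 paste(ps, collapse = "/")))
      }
    }
  }
})

test_that("masking a modality omits its token and its encoder entirely", {
  mc <- tiny_model_config(mask = c("signal", "metadata"))
  set.seed(48)
  model <- model_init(mc)
  expect_null(model$weights$img)
  expect_null(model$weights$proj_image)
  expect_equal(nrow(model$weights$modality_emb$val), 2L)
  params <- ctgfuse:::model_trainable_params(model)
  expect_false(any(grepl("^img", names(params))))
  expect_error(fusion_config(modality_mask = character(0)), "non-empty")
})
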