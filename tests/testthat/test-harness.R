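test_that("the stratified split reproduces the canonical cohort sizes", {
  labels <- c(rep(1, 330), rep(0, 222))
  for (seed in c(0, 42, 3407)) {
    sp <- stratified_split(labels, split_spec(seed = seed))
    expect_length(sp$train, 331L)
    expect_length(sp$val, 110L)
    expect_length(sp$test, 111L)
    expect_equal(sum(labels[sp$train]), 198)
    expect_equal(sum(labels[sp$val]), 66)
    expect_equal(sum(labels[sp$test]), 66)
    expect_equal(sum(labels[sp$train] == 0), 133)
    expect_equal(sum(labels[sp$val] == 0), 44)
    expect_equal(sum(labels[sp$test] == 0), 45)
    expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
  }
})

test_that("splits are seed-deterministic, disjoint and proportion-preserving", {
  set.seed(61)
  for (i in 1:10) {
    n1 <- sample(10:80, 1); n0 <- sample(10:80, 1)
    labels <- sample(c(rep(1, n1), rep(0, n0)))
    sp1 <- stratified_split(labels, split_spec(seed = i))
    sp2 <- stratified_split(labels, split_spec(seed = i))
    expect_identical(sp1, sp2)
    expect_setequal(unlist(sp1), seq_along(labels))
    expect_equal(length(intersect(sp1$train, sp1$test)), 0L)
    # per-class floor/remainder counts
    for (cl in 0:1) {
      nc <- sum(labels == cl)
      expect_equal(sum(labels[sp1$train] == cl), floor(nc * 0.6))
      expect_equal(sum(labels[sp1$val] == cl), floor(nc * 0.2))
    }
    sp3 <- stratified_split(labels, split_spec(seed = i + 1000))
    expect_equal(lengths(sp3), lengths(sp1))
  }
  expect_error(stratified_split(c(1, 1, 1, 0, 0), split_spec()), "fewer than 3")
  expect_error(stratified_split(rep(1, 10), split_spec()), "both classes")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("training is seed-deterministic and the reconstruction path is live", {
  ds <- separable_world(n = 8, seed = 31)
  mc <- tiny_model_config(mask = c("signal", "metadata"))
  split <- list(train = 1:8, val = 1:8)
  tc <- train_config(batch_size = 4, max_epochs = 1, seeds = 0L)
  f1 <- train_model(ds, split, mc, tc, seed = 5)
  f2 <- train_model(ds, split, mc, tc, seed = 5)
  expect_identical(f1$log$train_loss[1], f2$log$train_loss[1])

  mc0 <- mc
  mc0$loss$recon_weight <- 0
  f3 <- train_model(ds, split, mc0, tc, seed = 5)
  v1 <- ctgfuse:::snapshot_params(ctgfuse:::collect_params(f1$model$weights$mae))
  v3 <- ctgfuse:::snapshot_params(ctgfuse:::collect_params(f3$model$weights$mae))
  expect_false(identical(v1, v3))   # lambda changes the parameter trajectory
})

test_that("metadata statistics and checkpoint selection never read the test set", {
  ds <- separable_world(n = 12, seed = 32)
  labels <- vapply(ds, `[[`, integer(1), "label")
  split <- stratified_split(labels, split_spec(seed = 1))
  mc <- tiny_model_config(mask = c("signal", "metadata"))
  tc <- train_config(batch_size = 4, max_epochs = 2, seeds = 0L)
  fit1 <- train_model(ds, split, mc, tc, seed = 2)

  ds2 <- ds
  for (i in split$test) {
    ds2[[i]]$fhr <- rev(ds2[[i]]$fhr)
    ds2[[i]]$metadata$age <- 99
    ds2[[i]]$metadata$diabetes <- 1 - ds2[[i]]$metadata$diabetes
  }
  expect_identical(fit_metadata_stats(ds[split$train]),
                   fit_metadata_stats(ds2[split$train]))
  fit2 <- train_model(ds2, split, mc, tc, seed = 2)
  expect_identical(ctgfuse:::snapshot_params(ctgfuse:::collect_params(fit1$model$weights)),
                   ctgfuse:::snapshot_params(ctgfuse:::collect_params(fit2$model$weights)))
  expect_identical(fit1$best_epoch, fit2$best_epoch)
})

test_that("run_experiment aggregates per-seed runs and round-trips as JSON", {
  ds <- separable_world(n = 12, seed = 33)
  mc <- tiny_model_config(mask = c("signal", "metadata"))
  tc <- train_config(batch_size = 4, max_epochs = 2, seeds = 0L)
  rep1 <- run_experiment(ds, mc, tc)
  expect_length(rep1$runs, 1L)
  expect_equal(unname(rep1$aggregate$sd[["auc"]]), 0)   # single run
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep1, path)
  back <- read_eval_report(path)
  expect_equal(back$aggregate$mean, rep1$aggregate$mean, tolerance = 1e-12)
  expect_equal(back$runs[[1]]$qi, rep1$runs[[1]]$qi, tolerance = 1e-12)
})

test_that("ablation axes mutate the configuration as documented", {
  base <- tiny_model_config()
  grid <- list(c(64, 16), c(64, 32), c(96, 24), c(128, 24), c(128, 32))
  for (ps in grid) {
    cfg <- ctgfuse:::apply_axis(base, "patch", ps)
    expect_equal(cfg$ctg$patch_length, as.integer(ps[1]))
    expect_equal(cfg$ctg$stride, as.integer(ps[2]))
  }
  cfg <- ctgfuse:::apply_axis(base, "modality_mask", c("metadata", "signal"))
  expect_equal(cfg$fusion$modality_mask, c("signal", "metadata"))  # fixed order
  cfg <- ctgfuse:::apply_axis(base, "lambda", 0)
  expect_equal(cfg$loss$recon_weight, 0)
  expect_error(ctgfuse:::apply_axis(base, "optimizer", "sgd"), "unknown ablation axis")
})

test_that("ablation_sweep emits one report per configuration", {
  ds <- separable_world(n = 12, seed = 34)
  mc <- tiny_model_config(mask = c("signal", "metadata"))
  tc <- train_config(batch_size = 4, max_epochs = 1, seeds = 0L)
  sw <- ablation_sweep(ds, mc, tc, axes = list(
    strategy = c("transformer", "concat", "add", "mlp")))
  expect_equal(nrow(sw$table), 4L)
  expect_equal(sw$table$value, c("transformer", "concat", "add", "mlp"))
  expect_true(all(is.finite(sw$table$auc)))
})
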