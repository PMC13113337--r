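# Experiment harness: stratified splitting, the seeded training loop with
# validation-based checkpoint selection, multi-seed experiments and ablation
# sweeps.

#' Split specification
#'
#' Per class: shuffle with the seed, take `floor(n_c * train)` for training
#' and `floor(n_c * val)` for validation; the remainder goes to test.  This
#' floor/remainder convention is the one that reproduces the canonical
#' 552-record cohort split 331/110/111 with per-class counts
#' (198,133)/(66,44)/(66,45) at ratios 6:2:2.
#'
#' @param train,val,test positive proportions summing to 1.
#' @param seed shuffle seed.
#' @export
split_spec <- function(train = 0.6, val = 0.2, test = 0.2, seed = 0L) {
  if (abs(train + val + test - 1) > 1e-9 || any(c(train, val, test) <= 0)) {
    abort_input("ratios must be positive and sum to 1")
  }
  structure(list(train = train, val = val, test = test, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' @param labels binary label vector (both classes must be present and each
#'   class needs at least 3 members).
#' @param spec a [split_spec()].
#' @return list of disjoint index vectors `train`, `val`, `test` partitioning
#'   `seq_along(labels)`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("both classes must be present", call. = FALSE)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(spec$seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < 3) {
        stop(sprintf("class %s has fewer than 3 members", cl), call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      n_tr <- floor(length(idx) * spec$train)
      n_va <- floor(length(idx) * spec$val)
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$val <- c(out$val, idx[n_tr + seq_len(n_va)])
      out$test <- c(out$test, idx[-seq_len(n_tr + n_va)])
    }
  })
  lapply(out, sort)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight decay folded into the Adam gradient.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param selection_metric validation metric for checkpoint selection:
#'   `"qi"` (default), `"auc"` or `"loss"`.
#' @param seeds seeds for the repeated-run experiment protocol.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         batch_size = 64L, max_epochs = 100L,
                         selection_metric = c("qi", "auc", "loss"),
                         seeds = c(0L, 42L, 3407L)) {
  selection_metric <- match.arg(selection_metric)
  if (learning_rate <= 0 || batch_size < 1 || max_epochs < 1) {
    abort_input("rates and sizes must be positive")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 selection_metric = selection_metric,
                 seeds = as.integer(seeds)),
            class = "train_config")
}

predict_probs <- function(model, feats) {
  vapply(feats, function(f) predict_record(model, f)$probability, numeric(1))
}

#' Evaluate a model on prepared features
#'
#' @param model a trained `ctg_model`.
#' @param feats prepared features from [prepare_features()].
#' @param threshold decision threshold on the abnormal probability.
#' @return a metric set (see [metric_set()]).
#' @export
evaluate_model <- function(model, feats, threshold = 0.5) {
  probs <- predict_probs(model, feats)
  labels <- vapply(feats, function(f) f$label, numeric(1))
  metric_set(labels, probs, threshold)
}

snapshot_params <- function(params) lapply(params, function(p) p$val)

restore_params <- function(params, snap) {
  for (k in seq_along(params)) params[[k]]$val <- snap[[k]]
  invisible(NULL)
}

#' Train a model
#'
#' Seeds every stochastic component (initialization, shuffling, dropout) from
#' `seed`, runs up to `max_epochs` epochs of Adam on the composite loss,
#' evaluates the selection metric on the validation split after every epoch
#' and returns the best-validation checkpoint.  Test indices are never read.
#'
#' @param records full record list.
#' @param split index list with `train` and `val` (e.g. from
#'   [stratified_split()]).
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param seed integer seed for this run.
#' @param preprocess_cfg a [preprocess_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint restored), `stats`
#'   (metadata statistics), `log` (per-epoch data frame), `best_epoch`.
#' @export
train_model <- function(records, split, config, tc = train_config(),
                        seed = 0L, preprocess_cfg = preprocess_config(),
                        verbose = FALSE) {
  labels_tr <- vapply(records[split$train], function(r) r$label, integer(1))
  labels_va <- vapply(records[split$val], function(r) r$label, integer(1))
  if (length(unique(labels_tr)) < 2 || length(unique(labels_va)) < 2) {
    stop("both classes required in train and validation splits", call. = FALSE)
  }
  stats <- fit_metadata_stats(records[split$train])
  feats_tr <- prepare_features(records[split$train], config, stats, preprocess_cfg)
  feats_va <- prepare_features(records[split$val], config, stats, preprocess_cfg)

  with_seed(seed, {
    model <- model_init(config)
    params <- model_trainable_params(model)
    opt <- adam_new(params, lr = tc$learning_rate, weight_decay = tc$weight_decay)
    n_tr <- length(feats_tr)
    better <- function(a, b) if (tc$selection_metric == "loss") a < b else a > b
    best_val <- if (tc$selection_metric == "loss") Inf else -Inf
    best_snap <- snapshot_params(params)
    best_epoch <- 0L
    log <- vector("list", tc$max_epochs)
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(n_tr)
      losses <- c()
      for (start in seq(1L, n_tr, by = tc$batch_size)) {
        batch <- feats_tr[ord[start:min(start + tc$batch_size - 1L, n_tr)]]
        tape <- ad_tape()
        loss <- model_batch_loss(tape, model, batch, train = TRUE)
        if (!is.finite(loss$total$val[1L, 1L])) {
          stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
               call. = FALSE)
        }
        zero_grads(params)
        ad_backward(tape, loss$total)
        adam_step(opt)
        losses <- c(losses, loss$total$val[1L, 1L])
      }
      probs_va <- predict_probs(model, feats_va)
      val_metric <- switch(tc$selection_metric,
        qi = classification_metrics(confusion(labels_va, as.integer(probs_va >= 0.5)))$qi,
        auc = roc_auc(probs_va, labels_va),
        loss = {
          tape <- ad_tape()
          model_batch_loss(tape, model, feats_va, train = FALSE)$total$val[1L, 1L]
        })
      if (better(val_metric, best_val)) {
        best_val <- val_metric
        best_snap <- snapshot_params(params)
        best_epoch <- epoch
      }
      log[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                 val_metric = val_metric)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val %s %.4f", epoch,
                        mean(losses), tc$selection_metric, val_metric))
      }
    }
    restore_params(params, best_snap)
    list(model = model, stats = stats, log = do.call(rbind, log),
         best_epoch = best_epoch, best_val = best_val, seed = seed)
  })
}

#' Run a multi-seed experiment
#'
#' For each seed: a fresh stratified split, training with validation-based
#' checkpoint selection, and test-set evaluation; results aggregated as
#' mean and standard deviation per metric.
#'
#' @param records full record list.
#' @param config a [model_config()].
#' @param tc a [train_config()] (its `seeds` drive the runs).
#' @param ratios a [split_spec()] template (its seed is replaced per run).
#' @param preprocess_cfg a [preprocess_config()].
#' @return an `eval_report`: per-seed metric sets plus the aggregate.
#' @export
run_experiment <- function(records, config, tc = train_config(),
                           ratios = split_spec(),
                           preprocess_cfg = preprocess_config()) {
  labels <- vapply(records, function(r) r$label, integer(1))
  runs <- lapply(tc$seeds, function(sd) {
    spec <- split_spec(ratios$train, ratios$val, ratios$test, seed = sd)
    split <- stratified_split(labels, spec)
    fit <- train_model(records, split, config, tc, seed = sd,
                       preprocess_cfg = preprocess_cfg)
    feats_te <- prepare_features(records[split$test], config, fit$stats,
                                 preprocess_cfg)
    m <- evaluate_model(fit$model, feats_te)
    m$seed <- sd
    m$best_epoch <- fit$best_epoch
    m
  })
  structure(list(runs = runs, aggregate = aggregate_runs(runs),
                 n_records = length(records), seeds = tc$seeds),
            class = "eval_report")
}

#' Serialize / read an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path file path.
#' @export
write_eval_report <- function(report, path) {
  payload <- list(
    runs = lapply(report$runs, function(r) {
      r$counts <- unclass(r$counts)
      r
    }),
    aggregate = list(mean = as.list(report$aggregate$mean),
                     sd = as.list(report$aggregate$sd)),
    n_records = report$n_records,
    seeds = report$seeds
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(list(
    runs = x$runs,
    aggregate = list(mean = unlist(x$aggregate$mean), sd = unlist(x$aggregate$sd)),
    n_records = x$n_records, seeds = unlist(x$seeds)
  ), class = "eval_report")
}

apply_axis <- function(config, axis, value) {
  switch(axis,
    modality_mask = {
      config$fusion$modality_mask <- MODALITIES[MODALITIES %in% value]
      config
    },
    strategy = { config$fusion$strategy <- value; config },
    signals = { config$ctg$channels <- value; config },
    patch = {
      config$ctg$patch_length <- as.integer(value[1])
      config$ctg$stride <- as.integer(value[2])
      config
    },
    heads = { config$fusion$n_heads <- as.integer(value); config },
    layers = { config$fusion$n_layers <- as.integer(value); config },
    epsilon = { config$loss$smoothing <- value; config },
    lambda = { config$loss$recon_weight <- value; config },
    abort_input("unknown ablation axis: ", axis)
  )
}

#' Ablation sweep
#'
#' Runs [run_experiment()] once per configuration obtained by varying one
#' axis at a time from the base configuration.  Supported axes:
#' `modality_mask` (list of masks), `strategy`, `signals` (list of channel
#' sets), `patch` (list of `c(P, S)` pairs), `heads`, `layers`, `epsilon`,
#' `lambda`.
#'
#' @param records full record list.
#' @param base_config a [model_config()].
#' @param tc a [train_config()].
#' @param axes named list of axis values.
#' @param ... passed to [run_experiment()].
#' @return list with `entries` (one per configuration: axis, value, report)
#'   and `table` (data frame of aggregate means).
#' @export
ablation_sweep <- function(records, base_config, tc = train_config(),
                           axes = list(), ...) {
  entries <- list()
  for (axis in names(axes)) {
    vals <- axes[[axis]]
    if (!is.list(vals)) vals <- as.list(vals)
    for (v in vals) {
      cfg <- apply_axis(base_config, axis, v)
      rep <- run_experiment(records, cfg, tc, ...)
      entries[[length(entries) + 1L]] <- list(
        axis = axis,
        value = paste(v, collapse = "+"),
        report = rep
      )
    }
  }
  table <- do.call(rbind, lapply(entries, function(e) {
    data.frame(axis = e$axis, value = e$value,
               t(e$report$aggregate$mean), check.names = FALSE)
  }))
  list(entries = entries, table = table)
}
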