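# Multimodal fusion: token projection, the fusion transformer (with concat /
# add / MLP ablation strategies), the two-logit softmax classification head,
# and the label-smoothing + auxiliary-reconstruction composite loss.

MODALITIES <- c("signal", "image", "metadata")

#' Fusion module configuration
#'
#' @param d_common shared token width d.
#' @param n_layers fusion transformer depth (default two layers).
#' @param n_heads attention heads (default four).
#' @param ffn_width feed-forward hidden width.
#' @param strategy `"transformer"` (default), `"concat"`, `"add"` or `"mlp"`.
#' @param modality_mask non-empty subset of
#'   `c("signal", "image", "metadata")`; a masked-out modality's token is
#'   omitted entirely (never zero-filled) and its encoder receives no
#'   gradient.
#' @param dropout dropout rate inside the fusion transformer during training.
#' @export
fusion_config <- function(d_common = 128L, n_layers = 2L, n_heads = 4L,
                          ffn_width = 256L,
                          strategy = c("transformer", "concat", "add", "mlp"),
                          modality_mask = MODALITIES, dropout = 0.1) {
  strategy <- match.arg(strategy)
  if (d_common %% n_heads != 0) abort_input("d_common must be divisible by n_heads")
  if (n_layers < 1) abort_input("n_layers must be >= 1")
  if (length(modality_mask) < 1 || !all(modality_mask %in% MODALITIES)) {
    abort_input("modality_mask must be a non-empty subset of signal/image/metadata")
  }
  modality_mask <- MODALITIES[MODALITIES %in% modality_mask]  # fixed order
  structure(list(d_common = as.integer(d_common), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), ffn_width = as.integer(ffn_width),
                 strategy = strategy, modality_mask = modality_mask,
                 dropout = dropout),
            class = "fusion_config")
}

#' Loss configuration
#'
#' Composite objective `L = L_cls + lambda * L_rec`: label-smoothing cross
#' entropy over the class logits plus a weighted mean-squared metadata
#' reconstruction penalty.
#' @param smoothing label-smoothing factor epsilon in `[0, 1)`.
#' @param recon_weight reconstruction weight lambda (`>= 0`).
#' @param n_classes number of classes C.
#' @export
loss_config <- function(smoothing = 0.1, recon_weight = 0.5, n_classes = 2L) {
  if (smoothing < 0 || smoothing >= 1) abort_input("smoothing must be in [0, 1)")
  if (recon_weight < 0) abort_input("recon_weight must be >= 0")
  structure(list(smoothing = smoothing, recon_weight = recon_weight,
                 n_classes = as.integer(n_classes)),
            class = "loss_config")
}

#' Smooth a class label into a soft target
#'
#' The true class receives `1 - eps`; every other class receives
#' `eps / (C - 1)`.  Entries sum to one.
#' @param y integer label in `0 .. C-1`.
#' @param eps smoothing factor.
#' @param C number of classes.
#' @export
smooth_labels <- function(y, eps = 0.1, C = 2L) {
  if (length(y) != 1L || is.na(y) || !(y %in% 0:(C - 1L))) {
    abort_input("y must be a single class label in 0..C-1")
  }
  out <- rep(eps / (C - 1L), C)
  out[y + 1L] <- 1 - eps
  out
}

#' Project modality feature vectors into the shared token space
#'
#' Three independent linear maps; rows stacked in the fixed order signal,
#' image, metadata.
#'
#' @param g_ctg,f_img,z_m modality feature vectors.
#' @param weights list with linear layers `proj_signal`, `proj_image`,
#'   `proj_metadata` (from [model_init()]).
#' @return a 3 x d matrix.
#' @export
project_tokens <- function(g_ctg, f_img, z_m, weights) {
  tape <- ad_tape()
  proj <- function(v, lin) {
    if (length(v) != nrow(lin$W$val)) abort_input("projection dimension mismatch")
    ad_linear(tape, ad_const(matrix(v, 1L)), lin)$val
  }
  rbind(proj(g_ctg, weights$proj_signal),
        proj(f_img, weights$proj_image),
        proj(z_m, weights$proj_metadata))
}

#' Fuse projected tokens with the fusion transformer
#'
#' Adds the learnable modality embedding, applies `n_layers` post-norm
#' residual blocks (LayerNorm after each residual sum) and mean-pools over
#' the token dimension.
#'
#' @param X0 `n_tokens x d` matrix of projected tokens.
#' @param config a [fusion_config()].
#' @param weights fusion weights (from [model_init()]: `modality_emb`,
#'   `blocks`).
#' @return fused representation, numeric vector of length d.
#' @export
fuse <- function(X0, config, weights) {
  tape <- ad_tape()
  H <- ad_axpy(tape, ad_const(X0), weights$modality_emb)
  H <- forward_encoder_stack(tape, H, weights$blocks, config$n_heads)
  as.numeric(ad_mean_rows(tape, H)$val)
}

#' Baseline fusion strategies
#'
#' `concat` stacks the tokens into one `n*d` vector, `add` sums them
#' elementwise (permutation invariant), `mlp` applies a two-layer perceptron
#' to the concatenation.
#'
#' @param tokens list of equal-length numeric token vectors.
#' @param strategy `"concat"`, `"add"` or `"mlp"`.
#' @param weights for `"mlp"`, a list with linear layers `fc1`, `fc2`.
#' @export
fuse_baseline <- function(tokens, strategy, weights = NULL) {
  if (!strategy %in% c("concat", "add", "mlp")) {
    abort_input("unknown fusion strategy: ", strategy)
  }
  if (strategy == "concat") return(unlist(tokens, use.names = FALSE))
  if (strategy == "add") return(Reduce(`+`, tokens))
  tape <- ad_tape()
  x <- ad_const(matrix(unlist(tokens), 1L))
  h <- ad_relu(tape, ad_linear(tape, x, weights$fc1))
  as.numeric(ad_linear(tape, h, weights$fc2)$val)
}

#' Classify a fused representation
#'
#' Two-logit linear head; class probabilities by softmax; the reported
#' probability is the abnormal class.
#' @param h_fuse fused representation vector.
#' @param weights list with the linear layer `classifier`.
#' @export
classify <- function(h_fuse, weights) {
  tape <- ad_tape()
  logits <- as.numeric(ad_linear(tape, ad_const(matrix(h_fuse, 1L)),
                                 weights$classifier)$val)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  list(logits = logits, probability = p[2L])
}

#' Composite training loss
#'
#' `L = L_cls + lambda * L_rec` with `L_cls` the label-smoothing cross
#' entropy averaged over the batch and `L_rec` the per-sample squared-L2
#' metadata reconstruction error averaged over the batch.
#'
#' @param logits `M x C` logit matrix.
#' @param labels integer labels in `0..C-1`.
#' @param recon,targets `M x 4` reconstruction and standardized-metadata
#'   matrices (or `NULL` when the metadata branch is masked).
#' @param config a [loss_config()].
#' @return list with `total`, `cls`, `rec`.
#' @export
composite_loss <- function(logits, labels, recon = NULL, targets = NULL,
                           config = loss_config()) {
  logits <- as.matrix(logits)
  soft <- t(vapply(labels, smooth_labels, numeric(config$n_classes),
                   eps = config$smoothing, C = config$n_classes))
  z <- logits - apply(logits, 1L, max)
  logp <- z - log(rowSums(exp(z)))
  cls <- -sum(soft * logp) / nrow(logits)
  rec <- if (is.null(recon)) 0 else sum((as.matrix(recon) - as.matrix(targets))^2) / nrow(logits)
  list(total = cls + config$recon_weight * rec, cls = cls, rec = rec)
}

# ---- full model assembly ---------------------------------------------------

#' Full model configuration
#'
#' Bundles the per-branch encoder configurations, the fusion and loss
#' configurations, the GADF imaging configuration and the segment length the
#' model is built for.
#'
#' @param ctg a [ctg_encoder_config()].
#' @param image an [image_encoder_config()].
#' @param metadata a [metadata_encoder_config()].
#' @param fusion a [fusion_config()].
#' @param loss a [loss_config()].
#' @param gadf a [gadf_config()]; defaults to the image encoder's input size
#'   with the fast path enabled for the tiny backbone.
#' @param segment_length series length the CTG encoder is built for.
#' @export
model_config <- function(ctg = ctg_encoder_config(),
                         image = image_encoder_config(),
                         metadata = metadata_encoder_config(),
                         fusion = fusion_config(),
                         loss = loss_config(),
                         gadf = NULL,
                         segment_length = 7200L) {
  if (is.null(gadf)) {
    gadf <- gadf_config(out_size = image$input_size,
                        fast_path = image$backbone == "tiny")
  }
  if (gadf$out_size != image$input_size) {
    abort_input("gadf out_size must match the image encoder input size")
  }
  structure(list(ctg = ctg, image = image, metadata = metadata,
                 fusion = fusion, loss = loss, gadf = gadf,
                 segment_length = as.integer(segment_length)),
            class = "model_config")
}

#' Initialize all model weights
#'
#' Draws from the current RNG stream; seed before calling for reproducible
#' initialization.  Only the branches present in the fusion modality mask are
#' instantiated.
#'
#' @param config a [model_config()].
#' @return a `ctg_model`: config plus nested weight lists.
#' @export
model_init <- function(config) {
  fz <- config$fusion
  d <- fz$d_common
  w <- list()
  if ("signal" %in% fz$modality_mask) {
    w$ctg <- ctg_encoder_init(config$ctg, config$segment_length)
    w$proj_signal <- init_linear(length(config$ctg$channels) * config$ctg$d_model, d)
  }
  if ("image" %in% fz$modality_mask) {
    w$img <- image_encoder_init(config$image)
    w$proj_image <- init_linear(config$image$out_dim, d)
  }
  if ("metadata" %in% fz$modality_mask) {
    w$mae <- metadata_ae_init(config$metadata)
    w$proj_metadata <- init_linear(config$metadata$latent_dim, d)
  }
  n_tok <- length(fz$modality_mask)
  head_in <- d
  if (fz$strategy == "transformer") {
    w$modality_emb <- init_embedding(n_tok, d)
    w$blocks <- init_encoder_stack(fz$n_layers, d, fz$ffn_width)
  } else if (fz$strategy == "concat") {
    head_in <- n_tok * d
  } else if (fz$strategy == "mlp") {
    w$mlp <- list(fc1 = init_linear(n_tok * d, fz$ffn_width),
                  fc2 = init_linear(fz$ffn_width, d))
  }
  w$classifier <- init_linear(head_in, config$loss$n_classes)
  structure(list(config = config, weights = w), class = "ctg_model")
}

# Forward pass for one record's prepared features.  Returns ad nodes.
model_forward_record <- function(tape, model, feat, train = FALSE) {
  cfg <- model$config
  w <- model$weights
  mask <- cfg$fusion$modality_mask
  tokens <- list()
  recon <- NULL
  if ("signal" %in% mask) {
    g <- forward_ctg(tape, feat$fhr, feat$uc, w$ctg, cfg$ctg, train)
    tokens$signal <- ad_linear(tape, g, w$proj_signal)
  }
  if ("image" %in% mask) {
    f <- forward_image(tape, feat$image, w$img, cfg$image, train)
    tokens$image <- ad_linear(tape, f, w$proj_image)
  }
  if ("metadata" %in% mask) {
    xm <- ad_const(matrix(feat$meta, 1L))
    z <- forward_metadata_enc(tape, xm, w$mae)
    tokens$metadata <- ad_linear(tape, z, w$proj_metadata)
    if (train) recon <- forward_metadata_dec(tape, z, w$mae)
  }
  st <- cfg$fusion$strategy
  h <- if (st == "transformer") {
    H <- ad_axpy(tape, ad_rbind(tape, tokens), w$modality_emb)
    H <- forward_encoder_stack(tape, H, w$blocks, cfg$fusion$n_heads,
                               cfg$fusion$dropout, train)
    ad_mean_rows(tape, H)
  } else if (st == "concat") {
    ad_cbind(tape, tokens)
  } else if (st == "add") {
    Reduce(function(a, b) ad_axpy(tape, a, b), tokens)
  } else {
    x <- ad_cbind(tape, tokens)
    ad_linear(tape, ad_relu(tape, ad_linear(tape, x, w$mlp$fc1)), w$mlp$fc2)
  }
  logits <- ad_linear(tape, h, w$classifier)
  list(logits = logits, recon = recon, h_fuse = h)
}

#' Predict a single record's class probability
#'
#' Evaluation-mode forward pass; the reconstruction pathway is skipped.
#'
#' @param model a `ctg_model`.
#' @param feat prepared features from [prepare_features()].
#' @return list with `logits` (length-C), `probability` (abnormal class),
#'   and `h_fuse`.
#' @export
predict_record <- function(model, feat) {
  tape <- ad_tape()
  out <- model_forward_record(tape, model, feat, train = FALSE)
  logits <- as.numeric(out$logits$val)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  list(logits = logits, probability = p[2L], h_fuse = as.numeric(out$h_fuse$val))
}

#' Prepare a record's model inputs
#'
#' Preprocesses the channels, renders the GADF image of the cleaned FHR at
#' the encoder's input size, and standardizes the metadata with
#' training-split statistics.
#'
#' @param records list of `ctg_record`.
#' @param config a [model_config()].
#' @param stats `metadata_stats` fitted on the training split.
#' @param preprocess_cfg a [preprocess_config()].
#' @return list of feature lists (`fhr`, `uc`, `image`, `meta`, `label`).
#' @export
prepare_features <- function(records, config, stats,
                             preprocess_cfg = preprocess_config()) {
  mask <- config$fusion$modality_mask
  lapply(records, function(r) {
    pp <- preprocess_record(r, preprocess_cfg)
    feat <- list(fhr = pp$record$fhr, uc = pp$record$uc, label = r$label,
                 record_id = r$record_id)
    if ("image" %in% mask) feat$image <- fhr_to_gadf(pp$record$fhr, config$gadf)
    if ("metadata" %in% mask) feat$meta <- standardize_metadata(r$metadata, stats)
    feat
  })
}

# Trainable parameters, honouring the image fine-tuning strategy.  With
# partial fine-tuning the early image-backbone stages are frozen: they are
# excluded from the optimizer and marked untracked so gradients never
# accumulate in them.
model_trainable_params <- function(model, freeze = TRUE) {
  all <- collect_params(model$weights)
  cfg <- model$config$image
  if (!is.null(model$weights$img) && cfg$backbone == "resnet" &&
      cfg$fine_tune == "partial") {
    frozen <- grepl("^img\\.", names(all)) & !grepl("^img\\.layer[34]\\.", names(all))
    if (freeze) for (p in all[frozen]) p$track <- FALSE
    return(all[!frozen])
  }
  all
}

# Batched training loss over a list of prepared features (ad node).
model_batch_loss <- function(tape, model, feats, train = TRUE) {
  cfg <- model$config
  outs <- lapply(feats, function(f) model_forward_record(tape, model, f, train))
  logits <- ad_rbind(tape, lapply(outs, function(o) o$logits))
  soft <- t(vapply(feats, function(f) {
    smooth_labels(f$label, cfg$loss$smoothing, cfg$loss$n_classes)
  }, numeric(cfg$loss$n_classes)))
  cls <- ad_lsce(tape, logits, soft)
  has_rec <- cfg$loss$recon_weight > 0 && !is.null(outs[[1]]$recon)
  if (has_rec) {
    recon <- ad_rbind(tape, lapply(outs, function(o) o$recon))
    tgt <- t(vapply(feats, function(f) f$meta, numeric(length(feats[[1]]$meta))))
    rec <- ad_mse_rows(tape, recon, tgt)
    total <- ad_axpy(tape, cls, rec, cfg$loss$recon_weight)
  } else {
    rec <- NULL
    total <- cls
  }
  list(total = total, cls = cls, rec = rec)
}
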