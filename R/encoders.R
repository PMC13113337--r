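# Modality-specific encoders: the patch-based channel-independent transformer
# for CTG signals, the residual-network (or desk-scale MLP) image encoder for
# GADF images, and the maternal-metadata standardizer + autoencoder.

# ---- CTG signal encoder ----------------------------------------------------

#' CTG encoder configuration
#'
#' A patch-based time-series transformer: each instance-normalized channel is
#' split into overlapping patches of length `patch_length` with stride
#' `stride`, linearly embedded into `d_model` dimensions, given learnable
#' positional embeddings, and run through a transformer encoder *shared across
#' channels* (channel-independent forward, shared weights).  Global average
#' pooling over patches yields one `d_model` vector per channel; channel
#' vectors are concatenated.
#'
#' @param patch_length patch length P in samples.
#' @param stride stride S in samples (`1 <= S <= P`).
#' @param d_model embedding width (divisible by `n_heads`).
#' @param n_layers encoder depth.
#' @param n_heads attention heads.
#' @param ffn_width feed-forward hidden width.
#' @param dropout dropout rate used during training.
#' @param eps normalization guard.
#' @param channels which channels feed the encoder (`c("fhr","uc")` or
#'   `"fhr"` for the FHR-only ablation).
#' @export
ctg_encoder_config <- function(patch_length = 64L, stride = 32L,
                               d_model = 128L, n_layers = 3L, n_heads = 4L,
                               ffn_width = 256L, dropout = 0.1, eps = 1e-5,
                               channels = c("fhr", "uc")) {
  if (stride < 1 || stride > patch_length) abort_input("require 1 <= stride <= patch_length")
  if (d_model %% n_heads != 0) abort_input("d_model must be divisible by n_heads")
  if (!all(channels %in% c("fhr", "uc")) || length(channels) < 1) {
    abort_input("channels must be a non-empty subset of c('fhr','uc')")
  }
  structure(list(patch_length = as.integer(patch_length),
                 stride = as.integer(stride), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 ffn_width = as.integer(ffn_width), dropout = dropout,
                 eps = eps, channels = channels),
            class = "ctg_encoder_config")
}

#' Per-channel instance normalization
#'
#' Z-scores a channel with its own mean and population (divide-by-n) standard
#' deviation, guarded by `eps`; a constant channel maps to all zeros.
#' Removes inter-subject baseline and amplitude differences.
#'
#' @param x numeric vector.
#' @param eps variance guard.
#' @export
instance_normalize <- function(x, eps = 1e-5) {
  if (length(x) == 0L) abort_input("empty channel")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  (x - mu) / sqrt(v + eps)
}

#' Number of patches covering a series
#'
#' `N = ceiling((L - P) / S) + 1`, the trailing partial patch completed by
#' zero padding (equals `(L - P)/S + 1` exactly when `S` divides `L - P`).
#' @param L series length.
#' @param P patch length.
#' @param S stride.
#' @export
patch_count <- function(L, P, S) {
  if (P > L) abort_input("patch length exceeds series length")
  as.integer(ceiling((L - P) / S) + 1)
}

#' Split a series into overlapping patches
#'
#' Patch `i` covers samples `(i-1)*S + 1 ... (i-1)*S + P`; the sequence tail
#' is zero padded so the last patch is full.
#'
#' @param x numeric vector (normalize first).
#' @param P patch length.
#' @param S stride.
#' @return an `N x P` matrix, one patch per row.
#' @export
patchify <- function(x, P, S) {
  L <- length(x)
  N <- patch_count(L, P, S)
  need <- (N - 1L) * S + P
  if (need > L) x <- c(x, rep(0, need - L))
  idx <- outer((seq_len(N) - 1L) * S, seq_len(P), "+")
  matrix(x[idx], N, P)
}

#' Initialize CTG encoder weights
#'
#' @param config a [ctg_encoder_config()].
#' @param segment_length series length L the encoder is built for (fixes the
#'   positional-embedding table).
#' @export
ctg_encoder_init <- function(config, segment_length) {
  N <- patch_count(segment_length, config$patch_length, config$stride)
  list(embed = init_linear(config$patch_length, config$d_model),
       pos = init_embedding(N, config$d_model),
       blocks = init_encoder_stack(config$n_layers, config$d_model, config$ffn_width),
       n_patches = N, segment_length = as.integer(segment_length))
}

forward_ctg_channel <- function(tape, x, weights, config, train = FALSE) {
  xn <- instance_normalize(x, config$eps)
  Pm <- patchify(xn, config$patch_length, config$stride)
  Z <- ad_linear(tape, ad_const(Pm), weights$embed)
  H <- ad_axpy(tape, Z, weights$pos)
  H <- forward_encoder_stack(tape, H, weights$blocks, config$n_heads,
                             config$dropout, train, config$eps)
  ad_mean_rows(tape, H)
}

forward_ctg <- function(tape, fhr, uc, weights, config, train = FALSE) {
  chans <- list(fhr = fhr, uc = uc)[config$channels]
  pooled <- lapply(chans, function(x) {
    forward_ctg_channel(tape, x, weights, config, train)
  })
  if (length(pooled) == 1L) pooled[[1L]] else ad_cbind(tape, pooled)
}

#' Encode a CTG record into its signal feature vector
#'
#' Deterministic evaluation-mode forward pass: instance normalization,
#' patch embedding + positional embedding, the shared transformer encoder,
#' mean pooling per channel, channel concatenation (FHR then UC).
#'
#' @param fhr,uc preprocessed channels (equal length; `uc` may be `NULL` when
#'   `config$channels == "fhr"`).
#' @param config a [ctg_encoder_config()].
#' @param weights from [ctg_encoder_init()].
#' @return numeric vector of length `length(channels) * d_model`.
#' @export
encode_ctg <- function(fhr, uc, config, weights) {
  if ("uc" %in% config$channels) {
    if (is.null(uc) || length(fhr) != length(uc)) {
      abort_input("fhr and uc must be present with equal length")
    }
  }
  tape <- ad_tape()
  as.numeric(forward_ctg(tape, fhr, uc, weights, config, train = FALSE)$val)
}

# ---- metadata standardization and autoencoder ------------------------------

#' Fit metadata standardization statistics on the training split only
#'
#' Means and sample (`n-1`) standard deviations of age, gravidity and parity;
#' missing values are excluded from the statistics that later impute them.
#' Zero or undefined standard deviations are guarded to 1 with a warning.
#'
#' @param records list of `ctg_record` objects (the training split).
#' @export
fit_metadata_stats <- function(records) {
  if (length(records) < 2L) abort_input("need at least 2 training records")
  grab <- function(f) vapply(records, function(r) as.numeric(r$metadata[[f]] %||% NA), numeric(1))
  fields <- c("age", "gravidity", "parity")
  mu <- vapply(fields, function(f) mean(grab(f), na.rm = TRUE), numeric(1))
  sd_ <- vapply(fields, function(f) stats::sd(grab(f), na.rm = TRUE), numeric(1))
  bad <- !is.finite(sd_) | sd_ == 0
  if (any(bad)) {
    warning("zero-variance metadata field(s): ", paste(fields[bad], collapse = ", "),
            "; standard deviation guarded to 1")
    sd_[bad] <- 1
  }
  mu[!is.finite(mu)] <- 0
  structure(list(mean = mu, sd = sd_), class = "metadata_stats")
}

#' Standardize a metadata vector
#'
#' Age, gravidity and parity are z-scored with training-split statistics;
#' missing values are imputed with the training mean first (hence standardize
#' to 0).  The binary diabetes indicator passes through unchanged (missing
#' diabetes defaults to 0).
#'
#' @param raw a [maternal_metadata()].
#' @param stats a `metadata_stats` object from [fit_metadata_stats()].
#' @return numeric 4-vector `(age', gravidity', parity', diabetes)`.
#' @export
standardize_metadata <- function(raw, stats) {
  z <- function(f) {
    v <- as.numeric(raw[[f]] %||% NA)
    if (is.na(v)) v <- stats$mean[[f]]
    (v - stats$mean[[f]]) / stats$sd[[f]]
  }
  dia <- as.numeric(raw$diabetes %||% NA)
  if (is.na(dia)) dia <- 0
  c(z("age"), z("gravidity"), z("parity"), dia)
}

#' Metadata autoencoder configuration
#'
#' Encoder 4 -> `hidden` (ReLU) -> `latent_dim` linear; mirror-image decoder.
#' At inference only the latent vector feeds fusion; the reconstruction is a
#' training-time regularizer.
#' @param input_dim,hidden,latent_dim layer widths.
#' @export
metadata_encoder_config <- function(input_dim = 4L, hidden = 64L, latent_dim = 32L) {
  if (any(c(input_dim, hidden, latent_dim) <= 0)) abort_input("dims must be positive")
  structure(list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 latent_dim = as.integer(latent_dim)),
            class = "metadata_encoder_config")
}

#' @rdname metadata_encoder_config
#' @param config a `metadata_encoder_config`.
#' @export
metadata_ae_init <- function(config = metadata_encoder_config()) {
  list(enc1 = init_linear(config$input_dim, config$hidden),
       enc2 = init_linear(config$hidden, config$latent_dim),
       dec1 = init_linear(config$latent_dim, config$hidden),
       dec2 = init_linear(config$hidden, config$input_dim))
}

forward_metadata_enc <- function(tape, x, weights) {
  h <- ad_relu(tape, ad_linear(tape, x, weights$enc1))
  ad_linear(tape, h, weights$enc2)
}

forward_metadata_dec <- function(tape, z, weights) {
  h <- ad_relu(tape, ad_linear(tape, z, weights$dec1))
  ad_linear(tape, h, weights$dec2)
}

#' Encode / decode metadata through the autoencoder
#'
#' @param x standardized 4-vector (for `encode_metadata`) or latent vector
#'   (for `decode_metadata`).
#' @param weights from [metadata_ae_init()].
#' @export
encode_metadata <- function(x, weights) {
  tape <- ad_tape()
  as.numeric(forward_metadata_enc(tape, ad_const(matrix(x, 1L)), weights)$val)
}

#' @rdname encode_metadata
#' @export
decode_metadata <- function(x, weights) {
  tape <- ad_tape()
  as.numeric(forward_metadata_dec(tape, ad_const(matrix(x, 1L)), weights)$val)
}

# ---- image encoder ---------------------------------------------------------

#' Image encoder configuration
#'
#' Two backbones are provided.  `"resnet"` is the faithful bottleneck residual
#' network (depth 50/101/152, 2048-dimensional output, 224 x 224 input);
#' pretrained weights are loaded from `weights_path` when available, otherwise
#' random initialization is used.  `"tiny"` is a desk-scale two-layer
#' perceptron over the flattened (downsampled) image, used where CPU-budget
#' training is required; it is an engineering surrogate, not part of the
#' reference architecture.
#'
#' @param depth residual depth: 50, 101 or 152.
#' @param pretrained attempt to load weights from `weights_path`.
#' @param fine_tune `"full"` (all stages trainable) or `"partial"` (only the
#'   two deepest residual stages, layer3 and layer4, receive gradients).
#' @param backbone `"resnet"` or `"tiny"`.
#' @param input_size expected square image side (224 for resnet).
#' @param tiny_hidden,tiny_out widths of the tiny backbone.
#' @param normalize apply the affine `[-1,1] -> [0,1]` mapping followed by
#'   standard pretrained-backbone channel normalization (resnet only).
#' @param weights_path optional checkpoint path (`.rds`) for pretrained
#'   weights; never downloaded.
#' @export
image_encoder_config <- function(depth = 101L, pretrained = TRUE,
                                 fine_tune = c("full", "partial"),
                                 backbone = c("resnet", "tiny"),
                                 input_size = NULL,
                                 tiny_hidden = 64L, tiny_out = 64L,
                                 normalize = TRUE, weights_path = NULL) {
  fine_tune <- match.arg(fine_tune)
  backbone <- match.arg(backbone)
  if (backbone == "resnet") resnet_stage_blocks(depth)   # validates depth
  if (is.null(input_size)) input_size <- if (backbone == "resnet") 224L else 24L
  out_dim <- if (backbone == "resnet") 2048L else as.integer(tiny_out)
  structure(list(depth = as.integer(depth), pretrained = pretrained,
                 fine_tune = fine_tune, backbone = backbone,
                 input_size = as.integer(input_size),
                 tiny_hidden = as.integer(tiny_hidden),
                 tiny_out = as.integer(tiny_out),
                 normalize = normalize, weights_path = weights_path,
                 out_dim = out_dim),
            class = "image_encoder_config")
}

#' Initialize image-encoder weights
#'
#' @param config an [image_encoder_config()].
#' @export
image_encoder_init <- function(config) {
  if (config$backbone == "tiny") {
    d_in <- config$input_size^2
    return(list(fc1 = init_linear(d_in, config$tiny_hidden),
                fc2 = init_linear(config$tiny_hidden, config$tiny_out)))
  }
  net <- resnet_init(config$depth)
  if (isTRUE(config$pretrained)) {
    if (!is.null(config$weights_path) && file.exists(config$weights_path)) {
      loaded <- readRDS(config$weights_path)
      net <- load_param_values(net, loaded)
    } else {
      message("pretrained weights unavailable; using random initialization")
    }
  }
  net
}

# Copy numeric values from a plain nested list into matching ad_param slots.
load_param_values <- function(net, values) {
  for (nm in names(values)) {
    if (is.null(net[[nm]])) next
    if (is_ad_node(net[[nm]])) {
      net[[nm]]$val <- as.matrix(values[[nm]])
    } else if (is.list(values[[nm]])) {
      net[[nm]] <- load_param_values(net[[nm]], values[[nm]])
    }
  }
  net
}

# ImageNet channel statistics applied after the [-1,1] -> [0,1] mapping.
.imagenet_mean <- c(0.485, 0.456, 0.406)
.imagenet_sd <- c(0.229, 0.224, 0.225)

image_to_input <- function(image, config) {
  px <- image$pixels
  if (config$backbone == "tiny") {
    return(matrix(as.vector(px), 1L))
  }
  v <- (as.vector(px) + 1) / 2           # [-1,1] -> [0,1]
  x <- matrix(v, length(v), 3L)          # grayscale replicated to 3 channels
  if (isTRUE(config$normalize)) {
    x <- sweep(sweep(x, 2L, .imagenet_mean, "-"), 2L, .imagenet_sd, "/")
  }
  x
}

forward_image <- function(tape, image, weights, config, train = FALSE) {
  x <- ad_const(image_to_input(image, config))
  if (config$backbone == "tiny") {
    h <- ad_relu(tape, ad_linear(tape, x, weights$fc1))
    return(ad_linear(tape, h, weights$fc2))
  }
  forward_resnet(tape, x, weights, config$input_size, config$input_size)
}

#' Encode a GADF image into its feature vector
#'
#' Deterministic evaluation-mode forward pass through the configured backbone
#' (classification layer removed).
#'
#' @param image a `gadf_image` whose side equals `config$input_size`.
#' @param config an [image_encoder_config()].
#' @param weights from [image_encoder_init()].
#' @return numeric vector of length `config$out_dim` (2048 for resnet).
#' @export
encode_image <- function(image, config, weights) {
  if (image$size != config$input_size) {
    abort_input(sprintf("image must be %dx%d for this encoder",
                        config$input_size, config$input_size))
  }
  tape <- ad_tape()
  as.numeric(forward_image(tape, image, weights, config, train = FALSE)$val)
}

#' Trainable image-encoder parameters under the fine-tuning strategy
#'
#' With `fine_tune = "partial"` only the two deepest residual stages (layer3
#' and layer4) are trainable; with `"full"` the whole backbone is.  The tiny
#' backbone is always fully trainable.
#'
#' @param weights from [image_encoder_init()].
#' @param config an [image_encoder_config()].
#' @return named flat list of parameter nodes.
#' @export
image_trainable_params <- function(weights, config) {
  if (config$backbone == "tiny" || config$fine_tune == "full") {
    return(collect_params(weights))
  }
  collect_params(weights[c("layer3", "layer4")])
}
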