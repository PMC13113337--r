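# Shared reduced-scale configurations and worlds for training tests.
# Segment lengths and model widths are scaled down from the reference
# configuration (7200 samples, d_model 128) purely for CPU budget; the
# architecture is unchanged.

tiny_ctg_config <- function(...) {
  ctg_encoder_config(d_model = 32L, n_layers = 1L, n_heads = 4L,
                     ffn_width = 64L, ...)
}

tiny_model_config <- function(mask = c("signal", "image", "metadata"),
                              segment_length = 480L, strategy = "transformer") {
  model_config(
    ctg = tiny_ctg_config(),
    image = image_encoder_config(backbone = "tiny", input_size = 16L,
                                 tiny_hidden = 32L, tiny_out = 32L),
    fusion = fusion_config(d_common = 32L, n_layers = 2L, n_heads = 4L,
                           ffn_width = 64L, strategy = strategy,
                           modality_mask = mask),
    segment_length = segment_length
  )
}

# A small strongly-coupled world for separability tests.
separable_world <- function(n = 16L, seed = 11L, segment_length = 480L,
                            diabetes_prob = c(0, 1)) {
  generate_dataset(synthetic_config(
    n_records = n, abnormal_fraction = 0.5, seed = seed,
    segment_length = segment_length, contraction_period = 60,
    decel_depth = 40, diabetes_prob = diabetes_prob, age_shift = 8
  ))
}

make_gadf_image <- function(pixels) {
  structure(list(pixels = pixels, size = nrow(pixels),
                 source_length = nrow(pixels)),
            class = "gadf_image")
}
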