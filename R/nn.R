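# Layer constructors and transformer building blocks on top of the autodiff
# engine.  All initializers draw from the current RNG stream; callers seed it.

init_linear <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  list(
    W = ad_param(matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)),
    b = ad_param(matrix(0, 1L, d_out))
  )
}

init_layernorm <- function(d) {
  list(gamma = ad_param(matrix(1, 1L, d)), beta = ad_param(matrix(0, 1L, d)))
}

init_embedding <- function(n, d, sd = 0.02) {
  ad_param(matrix(stats::rnorm(n * d, 0, sd), n, d))
}

ad_linear <- function(tape, x, lin) {
  ad_add(tape, ad_matmul(tape, x, lin$W), lin$b)
}

init_mhsa <- function(d) {
  list(q = init_linear(d, d), k = init_linear(d, d),
       v = init_linear(d, d), o = init_linear(d, d))
}

init_ffn <- function(d, width) {
  list(fc1 = init_linear(d, width), fc2 = init_linear(width, d))
}

init_encoder_block <- function(d, ffn_width) {
  list(mhsa = init_mhsa(d), ln1 = init_layernorm(d),
       ffn = init_ffn(d, ffn_width), ln2 = init_layernorm(d))
}

init_encoder_stack <- function(n_layers, d, ffn_width) {
  lapply(seq_len(n_layers), function(i) init_encoder_block(d, ffn_width))
}

# Multi-head self-attention over an n x d token matrix: per head
# softmax(Q K^T / sqrt(d_h)) V, heads concatenated then linearly projected.
forward_mhsa <- function(tape, H, pars, n_heads, dropout = 0, train = FALSE) {
  d <- ncol(H$val)
  dh <- d %/% n_heads
  Q <- ad_linear(tape, H, pars$q)
  K <- ad_linear(tape, H, pars$k)
  V <- ad_linear(tape, H, pars$v)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ad_cols(tape, Q, idx)
    Kh <- ad_cols(tape, K, idx)
    Vh <- ad_cols(tape, V, idx)
    scores <- ad_scale(tape, ad_matmul_t(tape, Qh, Kh), 1 / sqrt(dh))
    A <- ad_softmax_rows(tape, scores)
    heads[[h]] <- ad_matmul(tape, A, Vh)
  }
  out <- ad_linear(tape, ad_cbind(tape, heads), pars$o)
  if (train && dropout > 0) out <- ad_dropout(tape, out, dropout)
  out
}

forward_ffn <- function(tape, H, pars, dropout = 0, train = FALSE) {
  h <- ad_relu(tape, ad_linear(tape, H, pars$fc1))
  if (train && dropout > 0) h <- ad_dropout(tape, h, dropout)
  ad_linear(tape, h, pars$fc2)
}

# Post-norm residual block: LayerNorm applied to the residual sums,
#   H~ = LN(H + MHSA(H));  H' = LN(H~ + FFN(H~)).
forward_encoder_block <- function(tape, H, pars, n_heads, dropout = 0,
                                  train = FALSE, eps = 1e-5) {
  attn <- forward_mhsa(tape, H, pars$mhsa, n_heads, dropout, train)
  H1 <- ad_layernorm(tape, ad_axpy(tape, H, attn), pars$ln1$gamma, pars$ln1$beta, eps)
  ffw <- forward_ffn(tape, H1, pars$ffn, dropout, train)
  ad_layernorm(tape, ad_axpy(tape, H1, ffw), pars$ln2$gamma, pars$ln2$beta, eps)
}

forward_encoder_stack <- function(tape, H, blocks, n_heads, dropout = 0,
                                  train = FALSE, eps = 1e-5) {
  for (blk in blocks) {
    H <- forward_encoder_block(tape, H, blk, n_heads, dropout, train, eps)
  }
  H
}
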