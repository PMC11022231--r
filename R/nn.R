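# Layers and optimizer built on the autodiff primitives.
#
# Parameters live in one flat named list of matrices; a forward pass wraps
# them in leaf nodes (wrap_params) so each training step records a fresh
# tape. Layer helpers take the wrapped list P plus a name prefix.

init_store <- function() new.env(parent = emptyenv())

# Xavier-uniform initialization; fan counts follow the matrix shape.
init_linear <- function(params, name, din, dout, zero_bias = TRUE) {
  lim <- sqrt(6 / (din + dout))
  params[[paste0(name, ".W")]] <- matrix(stats::runif(din * dout, -lim, lim), din, dout)
  params[[paste0(name, ".b")]] <- matrix(0, 1, dout)
  params
}

init_conv <- function(params, name, cin, cout, k) {
  init_linear(params, name, k * k * cin, cout)
}

init_layernorm <- function(params, name, d) {
  params[[paste0(name, ".g")]] <- matrix(1, 1, d)
  params[[paste0(name, ".b")]] <- matrix(0, 1, d)
  params
}

wrap_params <- function(params) lapply(params, ad_leaf)

collect_grads <- function(nodes) lapply(nodes, function(n) {
  if (is.null(n$grad)) array(0, dim(n$val)) else n$grad
})

nn_linear <- function(P, name, x) {
  ad_add_bias(ad_matmul(x, P[[paste0(name, ".W")]]), P[[paste0(name, ".b")]])
}

nn_layernorm <- function(P, name, x) {
  ad_layernorm(x, P[[paste0(name, ".g")]], P[[paste0(name, ".b")]])
}

# x: node holding (h*w) x cin; returns list(x = node, h, w)
nn_conv <- function(P, name, x, h, w, k, stride = 1L, pad = k %/% 2L) {
  cols <- ad_im2col(x, h, w, k, stride, pad)
  out <- ad_add_bias(ad_matmul(cols, P[[paste0(name, ".W")]]), P[[paste0(name, ".b")]])
  list(x = out, h = attr(cols, "h_out"), w = attr(cols, "w_out"))
}

# 2x2 max pooling, stride 2
nn_maxpool2 <- function(x, h, w) {
  cols <- ad_im2col(x, h, w, 2L, 2L, 0L)
  cin <- ncol(x$val)
  picks <- lapply(1:4, function(o) ad_cols(cols, (seq_len(cin) - 1L) * 4L + o))
  out <- ad_pmax2(ad_pmax2(picks[[1]], picks[[2]]), ad_pmax2(picks[[3]], picks[[4]]))
  list(x = out, h = attr(cols, "h_out"), w = attr(cols, "w_out"))
}

# Multi-head attention. q, k, v are nodes (Lq x d, Lk x d, Lk x d).
# `gain` multiplies the 1/sqrt(dh) logit scale (an inverse softmax
# temperature): with freshly initialized projections the logits are nearly
# zero and attention starts uniform over the sequence, so gain > 1 lets a
# small model commit to a few tokens far earlier in training.
# Attention matrices are stashed in ctx$attn[[tag]] when ctx is supplied.
nn_mhsa <- function(P, name, q, k, v, nheads, ctx = NULL, tag = NULL, gain = 1) {
  d <- ncol(q$val)
  dh <- d %/% nheads
  Q <- nn_linear(P, paste0(name, ".q"), q)
  K <- nn_linear(P, paste0(name, ".k"), k)
  V <- nn_linear(P, paste0(name, ".v"), v)
  heads <- vector("list", nheads)
  aw <- if (!is.null(ctx)) vector("list", nheads)
  for (hh in seq_len(nheads)) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    Qh <- ad_cols(Q, idx); Kh <- ad_cols(K, idx); Vh <- ad_cols(V, idx)
    heads[[hh]] <- ad_attention(Qh, Kh, Vh, gain / sqrt(dh))
    if (!is.null(ctx)) aw[[hh]] <- attr(heads[[hh]], "attn")
  }
  if (!is.null(ctx) && !is.null(tag)) ctx$attn[[tag]] <- aw
  nn_linear(P, paste0(name, ".o"), ad_cbind(heads))
}

init_mhsa2 <- function(params, name, d) {
  for (p in c("q", "k", "v", "o")) params <- init_linear(params, paste0(name, ".", p), d, d)
  params
}

# Post-norm transformer encoder layer; pos is a constant node re-added to
# queries and keys at every layer (value stream carries no positions).
nn_encoder_layer <- function(P, name, x, pos, nheads, ctx = NULL, tag = NULL,
                             gain = 1) {
  qk <- ad_add(x, pos)
  att <- nn_mhsa(P, paste0(name, ".sa"), qk, qk, x, nheads, ctx, tag, gain)
  x <- nn_layernorm(P, paste0(name, ".ln1"), ad_add(x, att))
  ff <- nn_linear(P, paste0(name, ".ff2"), ad_relu(nn_linear(P, paste0(name, ".ff1"), x)))
  nn_layernorm(P, paste0(name, ".ln2"), ad_add(x, ff))
}

nn_decoder_layer <- function(P, name, tgt, qpos, mem, mempos, nheads, ctx = NULL,
                             tag = NULL, gain = 1) {
  qk <- ad_add(tgt, qpos)
  att <- nn_mhsa(P, paste0(name, ".sa"), qk, qk, tgt, nheads, gain = gain)
  tgt <- nn_layernorm(P, paste0(name, ".ln1"), ad_add(tgt, att))
  att <- nn_mhsa(P, paste0(name, ".ca"), ad_add(tgt, qpos), ad_add(mem, mempos), mem,
                 nheads, ctx, tag, gain)
  tgt <- nn_layernorm(P, paste0(name, ".ln2"), ad_add(tgt, att))
  ff <- nn_linear(P, paste0(name, ".ff2"), ad_relu(nn_linear(P, paste0(name, ".ff1"), tgt)))
  nn_layernorm(P, paste0(name, ".ln3"), ad_add(tgt, ff))
}

init_encoder_layer <- function(params, name, d, ffn) {
  params <- init_mhsa2(params, paste0(name, ".sa"), d)
  params <- init_layernorm(params, paste0(name, ".ln1"), d)
  params <- init_linear(params, paste0(name, ".ff1"), d, ffn)
  params <- init_linear(params, paste0(name, ".ff2"), ffn, d)
  init_layernorm(params, paste0(name, ".ln2"), d)
}

init_decoder_layer <- function(params, name, d, ffn) {
  params <- init_mhsa2(params, paste0(name, ".sa"), d)
  params <- init_mhsa2(params, paste0(name, ".ca"), d)
  for (l in c("ln1", "ln2", "ln3")) params <- init_layernorm(params, paste0(name, ".", l), d)
  params <- init_linear(params, paste0(name, ".ff1"), d, ffn)
  init_linear(params, paste0(name, ".ff2"), ffn, d)
}

# ---- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4, clip_norm = 0.1) {
  if (!is.null(clip_norm) && clip_norm > 0) {
    total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (total > clip_norm) grads <- lapply(grads, function(g) g * (clip_norm / total))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
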