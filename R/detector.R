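#' Detector configuration
#'
#' Assembles the whole set-prediction detector: backbone taps are projected
#' to `embed_dim` channels, position-encoded, flattened across scales, run
#' through a transformer encoder--decoder, and decoded into `num_queries`
#' object representations that two heads turn into class probabilities
#' (including the no-object class) and normalized boxes.
#'
#' @param image_size input side in pixels (images are square).
#' @param num_classes number of foreground classes `C`.
#' @param embed_dim token width `d`.
#' @param num_queries decoder slots `Q` (upper bound on objects per image).
#' @param num_encoder_layers,num_decoder_layers transformer depth.
#' @param num_heads attention heads (`embed_dim` must be divisible).
#' @param ffn_dim feed-forward hidden width.
#' @param backbone a [backbone_config()].
#' @param encoding an [encoding_config()] (built from `embed_dim` if `NULL`).
#' @param multi_scale use both backbone taps (`FALSE` keeps only the coarser
#'   tap: the single-scale baseline).
#' @param learned_query_embed supply each of the `Q` zero-initialized
#'   content queries with a learned positional embedding. With `FALSE` the
#'   queries are literal zeros and provably collapse to identical outputs;
#'   kept for audit only.
#' @param attn_gain inverse softmax temperature on every attention's
#'   logits (multiplies the usual `1/sqrt(d_head)` scale). Freshly
#'   initialized attention is nearly uniform over the token sequence, which
#'   leaves the decoder reading a global average of the image; a gain above
#'   1 sharpens attention from the start so queries commit to local
#'   evidence within a short training budget.
#' @param score_threshold inference-time foreground probability cutoff.
#' @return a `detector_config` list.
#' @export
detector_config <- function(image_size = 320L, num_classes = 7L,
                            embed_dim = 256L, num_queries = 32L,
                            num_encoder_layers = 6L, num_decoder_layers = 6L,
                            num_heads = 8L, ffn_dim = 4L * embed_dim,
                            backbone = backbone_config("full"),
                            encoding = NULL, multi_scale = TRUE,
                            learned_query_embed = TRUE, attn_gain = 1,
                            score_threshold = 0.5) {
  if (embed_dim %% num_heads != 0) stop("embed_dim must be divisible by num_heads")
  if (num_encoder_layers < 1 || num_decoder_layers < 1) stop("layers must be >= 1")
  if (is.null(encoding)) encoding <- encoding_config(embed_dim = embed_dim)
  structure(list(image_size = as.integer(image_size),
                 num_classes = as.integer(num_classes),
                 embed_dim = as.integer(embed_dim),
                 num_queries = as.integer(num_queries),
                 num_encoder_layers = as.integer(num_encoder_layers),
                 num_decoder_layers = as.integer(num_decoder_layers),
                 num_heads = as.integer(num_heads),
                 ffn_dim = as.integer(ffn_dim),
                 backbone = backbone, encoding = encoding,
                 multi_scale = isTRUE(multi_scale),
                 learned_query_embed = isTRUE(learned_query_embed),
                 attn_gain = attn_gain,
                 score_threshold = score_threshold),
            class = "detector_config")
}

#' Desk-scale detector configuration
#'
#' A small model sized for CPU training on 64 x 64 synthetic scenes: tiny
#' two-stage backbone, 64-wide embeddings, 1 encoder and 2 decoder layers,
#' 2 attention heads, 16 queries. The shallow encoder keeps the cost of
#' self-attention over the 320-token two-scale sequence compatible with
#' CPU-only training; the decoder keeps two layers so queries can both
#' pool evidence and de-duplicate against each other. The attention gain
#' defaults to 2 here: at this model size attention starts nearly uniform,
#' and the sharper logit scale lets it localize within the short training
#' budgets this configuration is meant for (see [detector_config()]).
#' @param num_classes foreground classes.
#' @param attn_gain attention logit gain (see [detector_config()]).
#' @param ... overrides passed to [detector_config()].
#' @export
tiny_detector_config <- function(num_classes = 5L,
                                 backbone = backbone_config("tiny"),
                                 attn_gain = 2, ...) {
  detector_config(image_size = 64L, num_classes = num_classes,
                  embed_dim = 64L, num_queries = 16L,
                  num_encoder_layers = 1L, num_decoder_layers = 2L,
                  num_heads = 2L, ffn_dim = 128L,
                  backbone = backbone, attn_gain = attn_gain, ...)
}

#' Initialize detector parameters
#'
#' Besides plain fan-balanced random weights, two initialization conventions
#' give the attention layers a spatial starting point (both are starting
#' values only -- every weight trains freely afterwards):
#'
#' * *anchor queries*: the learned query embeddings start as the positional
#'   codes of a `ceiling(sqrt(Q))`-per-side anchor grid (plus a little
#'   noise). By the cross-scale property of the encoding, each query's
#'   embedding then aligns with the positional signal of the corresponding
#'   relative location on every feature map.
#' * *aligned attention*: each attention's key projection starts equal to
#'   its query projection, so initial logits contain `p' W W^T q`, whose
#'   expectation over the random `W` is proportional to `p . q` -- a
#'   localized kernel in the positional codes. Cross-attention therefore
#'   starts focused around each query's anchor instead of uniform over the
#'   whole token sequence, which is what makes short training budgets
#'   workable: queries read local image content from the first step.
#'
#' @param config a [detector_config()].
#' @param seed RNG seed for the initialization.
#' @return flat named list of parameter matrices.
#' @export
detector_init <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$embed_dim
  params <- init_backbone(list(), config$backbone)
  taps <- tap_channels(config)
  for (s in seq_along(taps))
    params <- init_conv(params, sprintf("proj.%d", s), taps[s], d, 1L)
  for (l in seq_len(config$num_encoder_layers))
    params <- init_encoder_layer(params, sprintf("enc.%d", l), d, config$ffn_dim)
  for (l in seq_len(config$num_decoder_layers))
    params <- init_decoder_layer(params, sprintf("dec.%d", l), d, config$ffn_dim)
  for (l in seq_len(config$num_encoder_layers))
    params[[sprintf("enc.%d.sa.k.W", l)]] <- params[[sprintf("enc.%d.sa.q.W", l)]]
  for (l in seq_len(config$num_decoder_layers)) {
    params[[sprintf("dec.%d.sa.k.W", l)]] <- params[[sprintf("dec.%d.sa.q.W", l)]]
    params[[sprintf("dec.%d.ca.k.W", l)]] <- params[[sprintf("dec.%d.ca.q.W", l)]]
  }
  if (config$learned_query_embed) {
    Q <- config$num_queries
    g <- as.integer(ceiling(sqrt(Q)))
    anchors <- positional_signal(g, g, config$encoding)[seq_len(Q), , drop = FALSE]
    params[["qembed"]] <- anchors + 0.02 * matrix(stats::rnorm(Q * d), Q, d)
  }
  params <- init_linear(params, "head.cls", d, config$num_classes + 1L)
  params <- init_linear(params, "head.box1", d, d)
  params <- init_linear(params, "head.box2", d, d)
  init_linear(params, "head.box3", d, 4L)
}

tap_channels <- function(config) {
  cfg <- config$backbone
  ch <- vapply(cfg$tap_layers, function(s) stage_channels(cfg, s)["out"], integer(1))
  if (config$multi_scale) ch else ch[length(ch)]
}

# Full differentiable forward pass for one image.
# P: wrapped params; img_mat: (H*W) x 3 normalized matrix.
# Returns nodes: logits (Q x (C+1)), boxes (Q x 4), reps (Q x d).
detector_fwd <- function(P, config, img_mat, H, W, ctx = NULL) {
  taps <- backbone_fwd(P, config$backbone, new_node(img_mat, ng = TRUE), H, W)
  if (!config$multi_scale) taps <- taps[length(taps)]
  d <- config$embed_dim
  enc_cfg <- config$encoding
  proj <- vector("list", length(taps))
  pos <- vector("list", length(taps))
  for (s in seq_along(taps)) {
    t <- taps[[s]]
    pj <- nn_conv(P, sprintf("proj.%d", s), t$x, t$h, t$w, 1L)
    proj[[s]] <- pj$x
    pos[[s]] <- positional_signal(t$h, t$w, enc_cfg)
  }
  tokens <- if (length(proj) > 1L) ad_rbind(proj) else proj[[1]]
  pos_node <- ad_const(do.call(rbind, pos))
  x <- tokens
  gain <- config$attn_gain %||% 1
  for (l in seq_len(config$num_encoder_layers))
    x <- nn_encoder_layer(P, sprintf("enc.%d", l), x, pos_node, config$num_heads,
                          ctx, sprintf("enc.%d", l), gain)
  memory <- x
  Q <- config$num_queries
  tgt <- ad_const(matrix(0, Q, d))
  qpos <- if (config$learned_query_embed) P[["qembed"]] else ad_const(matrix(0, Q, d))
  for (l in seq_len(config$num_decoder_layers))
    tgt <- nn_decoder_layer(P, sprintf("dec.%d", l), tgt, qpos, memory, pos_node,
                            config$num_heads, ctx, sprintf("dec.%d", l), gain)
  reps <- tgt
  logits <- nn_linear(P, "head.cls", reps)
  bx <- ad_relu(nn_linear(P, "head.box1", reps))
  bx <- ad_relu(nn_linear(P, "head.box2", bx))
  boxes <- ad_sigmoid(nn_linear(P, "head.box3", bx))
  list(logits = logits, boxes = boxes, reps = reps, memory = memory)
}

#' Run the detector on one image (inference)
#'
#' @param params flat parameter list ([detector_init()]).
#' @param config the matching [detector_config()].
#' @param image `H x W x 3` array.
#' @param attention set `TRUE` to also return per-layer attention matrices.
#' @return list with `class_probs` (`Q x (C+1)`), `boxes` (`Q x 4`,
#'   normalized cxcywh), `reps` (`Q x d` object representations) and
#'   optionally `attn`.
#' @export
detector_forward <- function(params, config, image, attention = FALSE) {
  P <- lapply(params, ad_const)
  ctx <- if (attention) { e <- new.env(); e$attn <- list(); e }
  out <- detector_fwd(P, config, image_to_matrix(image),
                      dim(image)[1], dim(image)[2], ctx)
  res <- list(class_probs = softmax_rows(out$logits$val),
              boxes = out$boxes$val, reps = out$reps$val)
  if (attention) res$attn <- ctx$attn
  res
}

softmax_rows <- function(z) {
  rmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - rmax)
  e / rowSums(e)
}

#' Classification head applied to object representations
#'
#' One affine layer plus softmax over `C + 1` classes (the extra column is
#' the no-object class).
#' @param reps `n x d` matrix of object representations.
#' @param params,config detector parameters and config.
#' @return `n x (C+1)` probability matrix.
#' @export
classify_head <- function(reps, params, config) {
  z <- reps %*% params[["head.cls.W"]] +
    matrix(params[["head.cls.b"]], nrow(reps), config$num_classes + 1L, byrow = TRUE)
  softmax_rows(z)
}

#' Box head applied to object representations
#'
#' Three affine layers (ReLU between) with a sigmoid squashing every
#' coordinate into (0, 1).
#' @inheritParams classify_head
#' @return `n x 4` matrix of normalized `(cx, cy, w, h)` boxes.
#' @export
box_head <- function(reps, params, config) {
  mlp <- function(nm, x) x %*% params[[paste0(nm, ".W")]] +
    matrix(params[[paste0(nm, ".b")]], nrow(x), ncol(params[[paste0(nm, ".W")]]), byrow = TRUE)
  z <- pmax(mlp("head.box1", reps), 0)
  z <- pmax(mlp("head.box2", z), 0)
  1 / (1 + exp(-mlp("head.box3", z)))
}

#' Filter raw query predictions into detections
#'
#' Keeps queries whose most probable class is a foreground class with
#' probability at or above the threshold. Set prediction needs no
#' non-maximum suppression.
#'
#' @param class_probs `Q x (C+1)` matrix (last column = no-object).
#' @param boxes `Q x 4` normalized cxcywh.
#' @param score_threshold minimum foreground probability.
#' @return data.frame with `class_id` (0-based), `score`, and box columns.
#' @export
postprocess <- function(class_probs, boxes, score_threshold = 0.5) {
  C1 <- ncol(class_probs)
  arg <- max.col(class_probs, ties.method = "first")
  keep <- arg != C1 & class_probs[cbind(seq_len(nrow(class_probs)), arg)] >= score_threshold
  data.frame(class_id = arg[keep] - 1L,
             score = class_probs[cbind(which(keep), arg[keep])],
             cx = boxes[keep, 1], cy = boxes[keep, 2],
             w = boxes[keep, 3], h = boxes[keep, 4])
}

#' Transformer encoder over a token sequence
#'
#' @param tokens `L x d` matrix (projected, *not* yet position-enriched:
#'   the positional signal is re-added to queries and keys at every layer).
#' @param pos `L x d` positional signal matrix.
#' @param params,config detector parameters and config.
#' @param attention return attention matrices as well.
#' @return `L x d` encoded memory, or a list with `memory` and `attn`.
#' @export
encode_tokens <- function(tokens, pos, params, config, attention = FALSE) {
  P <- lapply(params, ad_const)
  ctx <- if (attention) { e <- new.env(); e$attn <- list(); e }
  x <- ad_const(tokens)
  pn <- ad_const(pos)
  for (l in seq_len(config$num_encoder_layers))
    x <- nn_encoder_layer(P, sprintf("enc.%d", l), x, pn, config$num_heads,
                          ctx, sprintf("enc.%d", l), config$attn_gain %||% 1)
  if (attention) list(memory = x$val, attn = ctx$attn) else x$val
}

#' Transformer decoder producing object representations
#'
#' Content queries start as a matrix of zeros; when the config enables
#' learned query embeddings they provide the positional component of each
#' query slot.
#'
#' @param memory `L x d` encoder output; `pos` its positional signal.
#' @param params,config detector parameters and config.
#' @return `Q x d` matrix of object representations.
#' @export
decode_queries <- function(memory, pos, params, config) {
  P <- lapply(params, ad_const)
  d <- config$embed_dim
  Q <- config$num_queries
  tgt <- ad_const(matrix(0, Q, d))
  qpos <- if (config$learned_query_embed) P[["qembed"]] else ad_const(matrix(0, Q, d))
  mem <- ad_const(memory)
  pn <- ad_const(pos)
  for (l in seq_len(config$num_decoder_layers))
    tgt <- nn_decoder_layer(P, sprintf("dec.%d", l), tgt, qpos, mem, pn,
                            config$num_heads, gain = config$attn_gain %||% 1)
  tgt$val
}
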