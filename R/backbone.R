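#' Backbone configuration
#'
#' Convolutional feature extractor with hierarchical-residual ("Res2Net")
#' blocks: each block splits its channels into `scale_groups` groups of
#' `group_width` channels; group 1 passes through, every later group is
#' convolved after receiving the previous group's output, so successive
#' groups see progressively larger receptive fields. Two stages are tapped
#' and fed to the detector neck.
#'
#' @param variant `"tiny"` (two stages, one block each, strides 4 and 8 --
#'   sized for CPU training) or `"full"` (four stages with 3/4/6/3 bottleneck
#'   blocks mirroring a 50-layer layout, taps at strides 8 and 32).
#' @param scale_groups number of channel groups per block (>= 2).
#' @param group_width channels per group in the first stage (the full
#'   default 26 reproduces the four-sets-of-26 split; tiny uses 8).
#' @param block_type `"res2net"` or `"plain"` (two plain 3x3 convolutions
#'   with a residual connection -- the single-scale baseline backbone).
#' @param tap_layers which two stages feed the neck.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(variant = c("tiny", "full"),
                            scale_groups = 4L,
                            group_width = NULL,
                            block_type = c("res2net", "plain"),
                            tap_layers = NULL) {
  variant <- match.arg(variant)
  block_type <- match.arg(block_type)
  if (scale_groups < 2L) stop("scale_groups must be >= 2")
  if (is.null(group_width)) group_width <- if (variant == "tiny") 8L else 26L
  if (variant == "tiny") {
    stages <- list(blocks = c(1L, 1L), width_mult = c(1L, 2L))
    if (is.null(tap_layers)) tap_layers <- c(1L, 2L)
  } else {
    stages <- list(blocks = c(3L, 4L, 6L, 3L), width_mult = c(1L, 2L, 4L, 8L))
    if (is.null(tap_layers)) tap_layers <- c(2L, 4L)
  }
  if (length(tap_layers) != 2L) stop("exactly two tap layers are required")
  if (any(tap_layers > length(stages$blocks))) stop("tap layer beyond last stage")
  structure(list(variant = variant, scale_groups = scale_groups,
                 group_width = group_width, block_type = block_type,
                 tap_layers = sort(tap_layers), stages = stages),
            class = "backbone_config")
}

# Per-stage channel plan. tiny: basic blocks at g*width; full: bottleneck
# blocks with inner width g*width*mult and output 256*mult.
stage_channels <- function(cfg, s) {
  inner <- cfg$scale_groups * cfg$group_width * cfg$stages$width_mult[s]
  if (cfg$variant == "tiny") c(inner = inner, out = inner)
  else c(inner = inner, out = 256L * cfg$stages$width_mult[s])
}

init_res2net_block <- function(params, name, cin, inner, cout, g, wg) {
  params <- init_conv(params, paste0(name, ".in"), cin, inner, 1L)
  for (i in 2:g) params <- init_conv(params, paste0(name, ".g", i), wg, wg, 3L)
  params <- init_conv(params, paste0(name, ".out"), inner, cout, 1L)
  if (cin != cout) params <- init_conv(params, paste0(name, ".res"), cin, cout, 1L)
  params
}

init_plain_block <- function(params, name, cin, cout) {
  params <- init_conv(params, paste0(name, ".c1"), cin, cout, 3L)
  params <- init_conv(params, paste0(name, ".c2"), cout, cout, 3L)
  if (cin != cout) params <- init_conv(params, paste0(name, ".res"), cin, cout, 1L)
  params
}

#' Hierarchical-residual block forward pass
#'
#' Channels after the entry 1x1 convolution are split into `scale_groups`
#' groups of equal width; group 1 is passed through unchanged, and each
#' group `i >= 2` is convolved (3x3) after adding the transformed output of
#' group `i - 1`. The groups are re-concatenated, mixed by a 1x1
#' convolution, and a residual connection wraps the whole block.
#'
#' @param P wrapped parameter list; @param name parameter prefix.
#' @param x node holding `(h*w) x cin`; `h`, `w` spatial size.
#' @param g,wg number of groups and channels per group.
#' @keywords internal
res2net_block_fwd <- function(P, name, x, h, w, g, wg, cout) {
  inn <- nn_conv(P, paste0(name, ".in"), x, h, w, 1L)
  z <- ad_relu(inn$x)
  ys <- vector("list", g)
  ys[[1]] <- ad_cols(z, 1:wg)
  prev <- NULL
  for (i in 2:g) {
    xi <- ad_cols(z, ((i - 1L) * wg + 1L):(i * wg))
    inp <- if (i == 2L) xi else ad_add(xi, prev)
    prev <- ad_relu(nn_conv(P, paste0(name, ".g", i), inp, h, w, 3L)$x)
    ys[[i]] <- prev
  }
  out <- nn_conv(P, paste0(name, ".out"), ad_cbind(ys), h, w, 1L)$x
  res <- if (is.null(P[[paste0(name, ".res.W")]])) x
         else nn_conv(P, paste0(name, ".res"), x, h, w, 1L)$x
  ad_relu(ad_add(out, res))
}

plain_block_fwd <- function(P, name, x, h, w) {
  z <- ad_relu(nn_conv(P, paste0(name, ".c1"), x, h, w, 3L)$x)
  z <- nn_conv(P, paste0(name, ".c2"), z, h, w, 3L)$x
  res <- if (is.null(P[[paste0(name, ".res.W")]])) x
         else nn_conv(P, paste0(name, ".res"), x, h, w, 1L)$x
  ad_relu(ad_add(z, res))
}

init_backbone <- function(params, cfg) {
  if (cfg$variant == "tiny") {
    stem_out <- 16L
    params <- init_conv(params, "bb.stem", 3L, stem_out, 3L)
  } else {
    stem_out <- 64L
    params <- init_conv(params, "bb.stem", 3L, stem_out, 7L)
  }
  cin <- stem_out
  for (s in seq_along(cfg$stages$blocks)) {
    ch <- stage_channels(cfg, s)
    params <- init_conv(params, sprintf("bb.s%d.entry", s), cin, ch["inner"], 3L)
    cin <- ch["inner"]
    for (b in seq_len(cfg$stages$blocks[s])) {
      nm <- sprintf("bb.s%d.b%d", s, b)
      if (cfg$block_type == "plain") {
        params <- init_plain_block(params, nm, cin, ch["out"])
      } else {
        wg <- ch["inner"] %/% cfg$scale_groups
        params <- init_res2net_block(params, nm, cin, ch["inner"], ch["out"],
                                     cfg$scale_groups, wg)
      }
      cin <- ch["out"]
    }
  }
  params
}

# Forward pass; img node holds (H*W) x 3. Returns taps: list of
# list(x = node, h, w, stride, channels) for the two configured stages.
backbone_fwd <- function(P, cfg, img, H, W) {
  if (cfg$variant == "tiny") {
    st <- nn_conv(P, "bb.stem", img, H, W, 3L, stride = 2L)
    x <- ad_relu(st$x); h <- st$h; w <- st$w; stride <- 2L
  } else {
    st <- nn_conv(P, "bb.stem", img, H, W, 7L, stride = 2L)
    x <- ad_relu(st$x)
    mp <- nn_maxpool2(x, st$h, st$w)
    x <- mp$x; h <- mp$h; w <- mp$w; stride <- 4L
  }
  taps <- list()
  for (s in seq_along(cfg$stages$blocks)) {
    entry_stride <- if (cfg$variant == "tiny" || s > 1L) 2L else 1L
    en <- nn_conv(P, sprintf("bb.s%d.entry", s), x, h, w, 3L, stride = entry_stride)
    x <- ad_relu(en$x); h <- en$h; w <- en$w
    stride <- stride * entry_stride
    ch <- stage_channels(cfg, s)
    for (b in seq_len(cfg$stages$blocks[s])) {
      nm <- sprintf("bb.s%d.b%d", s, b)
      x <- if (cfg$block_type == "plain") plain_block_fwd(P, nm, x, h, w)
           else res2net_block_fwd(P, nm, x, h, w, cfg$scale_groups,
                                  ch["inner"] %/% cfg$scale_groups, ch["out"])
    }
    if (s %in% cfg$tap_layers)
      taps[[length(taps) + 1L]] <- list(x = x, h = h, w = w, stride = stride,
                                        channels = ncol(x$val))
  }
  taps
}

#' Extract multi-scale feature maps from an image
#'
#' Runs the backbone forward (inference mode) and returns the two tapped
#' feature maps.
#'
#' @param image `H x W x 3` numeric array (0--255 or 0--1).
#' @param config a [backbone_config()].
#' @param params flat parameter list from [detector_init()]; when `NULL`, a
#'   fresh seeded initialization is used.
#' @param seed seed for the fresh initialization.
#' @return list of two feature maps: `values` (`(h*w) x C`, row-major),
#'   `h`, `w`, `stride`, `scale_id`.
#' @export
extract_features <- function(image, config = backbone_config(), params = NULL,
                             seed = 1L) {
  if (is.null(params)) {
    set.seed(seed)
    params <- init_backbone(list(), config)
  }
  P <- lapply(params, ad_const)
  img <- ad_const(image_to_matrix(image))
  taps <- backbone_fwd(P, config, img, dim(image)[1], dim(image)[2])
  lapply(seq_along(taps), function(s) {
    t <- taps[[s]]
    list(values = t$x$val, h = t$h, w = t$w, stride = t$stride, scale_id = s)
  })
}

#' Standalone hierarchical-residual block on a plain feature grid
#'
#' Convenience wrapper used for block-level inspection: applies one
#' seeded, randomly initialized block to `values` (`(h*w) x C`).
#'
#' @param values `(h*w) x C` matrix; `h`, `w` its grid size.
#' @param scale_groups,group_width block layout; `C` must equal
#'   `scale_groups * group_width`.
#' @param seed initialization seed.
#' @export
res2net_block <- function(values, h, w, scale_groups = 4L,
                          group_width = ncol(values) %/% scale_groups,
                          seed = 1L) {
  C <- ncol(values)
  if (C != scale_groups * group_width)
    stop("channel count ", C, " is not scale_groups * group_width (",
         scale_groups, " x ", group_width, ")")
  set.seed(seed)
  params <- init_res2net_block(list(), "blk", C, C, C, scale_groups, group_width)
  P <- lapply(params, ad_const)
  out <- res2net_block_fwd(P, "blk", ad_const(values), h, w, scale_groups,
                           group_width, C)
  out$val
}

# image array H x W x 3 -> (H*W) x 3 row-major matrix, normalized to [-1, 1]
image_to_matrix <- function(image) {
  if (length(dim(image)) != 3L) stop("image must be H x W x 3")
  H <- dim(image)[1]; W <- dim(image)[2]
  m <- matrix(aperm(image, c(2, 1, 3)), H * W, 3)
  if (max(m) > 1) m <- m / 255
  2 * m - 1
}

#' Project a feature map into the common embedding space
#'
#' Pointwise (1x1 convolution) linear map applied per spatial cell; each
#' scale owns its projection parameters.
#'
#' @param fmap feature map (`values`, `h`, `w`) as from [extract_features()].
#' @param embed_dim output channel count.
#' @param weights optional list with `W` (`C x embed_dim`) and `b`; a seeded
#'   random projection is used when omitted.
#' @param seed seed for the random projection.
#' @export
project <- function(fmap, embed_dim = 256L, weights = NULL, seed = 1L) {
  if (embed_dim < 1L) stop("embed_dim must be >= 1")
  C <- ncol(fmap$values)
  if (is.null(weights)) {
    set.seed(seed + (fmap$scale_id %||% 1L))
    lim <- sqrt(6 / (C + embed_dim))
    weights <- list(W = matrix(stats::runif(C * embed_dim, -lim, lim), C, embed_dim),
                    b = matrix(0, 1, embed_dim))
  }
  fmap$values <- fmap$values %*% weights$W +
    matrix(weights$b, nrow(fmap$values), embed_dim, byrow = TRUE)
  fmap
}

`%||%` <- function(a, b) if (is.null(a)) b else a
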