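#' Cross-scale positional encoding configuration
#'
#' Feature cells from grids of different resolutions must be told where they
#' sit in the *image*, not in their own grid, so that the encoder can attend
#' across scales. The scaled position of column `x` on a grid of width `w`
#' is `range_constant * x / w` (default `4 * pi`, i.e. two full sinusoid
#' periods across the image); identical relative locations on different
#' grids therefore receive identical phases. The phase is written into the
#' channels as a geometric-frequency sine/cosine stack: the x phase over one
#' channel band, the y phase over the other.
#'
#' @param embed_dim token width `d`.
#' @param split `"half"` splits channels into equal x/y bands;
#'   `"legacy153"` uses bands `[0,152]` / `[153, d-1]` (only meaningful for
#'   `d = 256`).
#' @param range_constant phase at the far edge of the image; default `4*pi`.
#' @param freq_base geometric base of the sinusoid frequency progression.
#' @return an `encoding_config` list.
#' @export
encoding_config <- function(embed_dim = 256, split = c("half", "legacy153"),
                            range_constant = 4 * pi, freq_base = 20) {
  split <- match.arg(split)
  xb <- if (split == "half") c(0L, embed_dim %/% 2L - 1L) else c(0L, 152L)
  yb <- c(xb[2] + 1L, embed_dim - 1L)
  if (yb[1] > yb[2]) stop("embed_dim too small for the requested band split")
  structure(list(embed_dim = embed_dim, x_band = xb, y_band = yb,
                 range_constant = range_constant, freq_base = freq_base),
            class = "encoding_config")
}

#' Scaled grid position for a channel (the cross-scale phase)
#'
#' Returns `range_constant * x_j / w_s` when channel `k` belongs to the
#' x band, `range_constant * y_j / h_s` when it belongs to the y band.
#' Positions are 0-based; the result lies in `[0, range_constant)`.
#'
#' @param x_j,y_j 0-based column/row of the cell on its grid.
#' @param w_s,h_s grid width/height at scale `s`.
#' @param k 0-based channel index.
#' @param config an [encoding_config()].
#' @export
scaled_position <- function(x_j, y_j, w_s, h_s, k, config = encoding_config()) {
  if (any(x_j < 0 | x_j >= w_s) || any(y_j < 0 | y_j >= h_s))
    stop("grid position out of range")
  in_x <- k >= config$x_band[1] & k <= config$x_band[2]
  in_y <- k >= config$y_band[1] & k <= config$y_band[2]
  if (any(!in_x & !in_y)) stop("channel index outside both bands")
  ifelse(in_x, config$range_constant * x_j / w_s, config$range_constant * y_j / h_s)
}

# Sinusoid expansion of a phase vector over a band of `width` channels:
# channel pair t gets sin/cos of phase * freq_base^(-2t/width).
band_signal <- function(phase, width, freq_base) {
  n_pairs <- width %/% 2L
  out <- matrix(0, length(phase), width)
  for (t in seq_len(n_pairs)) {
    f <- freq_base^(-2 * (t - 1) / width)
    out[, 2L * t - 1L] <- sin(phase * f)
    out[, 2L * t] <- cos(phase * f)
  }
  if (width %% 2L == 1L) {
    f <- freq_base^(-2 * n_pairs / width)
    out[, width] <- sin(phase * f)
  }
  out
}

#' Positional signal for an `h x w` grid
#'
#' @param h,w grid height and width.
#' @param config an [encoding_config()].
#' @return `(h*w) x embed_dim` matrix, rows in row-major order, every entry
#'   in `[-1, 1]`.
#' @export
positional_signal <- function(h, w, config = encoding_config()) {
  xs <- rep(0:(w - 1L), times = h)
  ys <- rep(0:(h - 1L), each = w)
  px <- config$range_constant * xs / w
  py <- config$range_constant * ys / h
  xw <- config$x_band[2] - config$x_band[1] + 1L
  yw <- config$y_band[2] - config$y_band[1] + 1L
  cbind(band_signal(px, xw, config$freq_base),
        band_signal(py, yw, config$freq_base))
}

#' Add the positional signal to a projected feature map
#'
#' @param pmap list with `values` (`(h*w) x d` matrix, row-major), `h`, `w`,
#'   and optionally `scale_id`.
#' @param config an [encoding_config()].
#' @return `pmap` with the positional signal added element-wise.
#' @export
encode_map <- function(pmap, config = encoding_config()) {
  if (ncol(pmap$values) != config$embed_dim)
    stop("projected map width does not match embed_dim")
  pmap$values <- pmap$values + positional_signal(pmap$h, pmap$w, config)
  pmap
}

#' Flatten and concatenate encoded maps into the transformer token sequence
#'
#' Maps are concatenated scale 1 first; bookkeeping vectors record the scale
#' and grid position of every token so the sequence can be unflattened.
#'
#' @param maps list of encoded maps (see [encode_map()]), all with equal `d`.
#' @return list with `tokens` (`L x d`), `scale_of_token`,
#'   `grid_position_of_token` (`L x 2`, 0-based x, y), and `shapes`.
#' @export
flatten_concat <- function(maps) {
  d <- unique(vapply(maps, function(m) ncol(m$values), integer(1)))
  if (length(d) != 1) stop("maps disagree on embedding width")
  tokens <- do.call(rbind, lapply(maps, function(m) m$values))
  scale_of <- unlist(lapply(seq_along(maps), function(s)
    rep(s, maps[[s]]$h * maps[[s]]$w)))
  pos <- do.call(rbind, lapply(maps, function(m)
    cbind(rep(0:(m$w - 1L), times = m$h), rep(0:(m$h - 1L), each = m$w))))
  list(tokens = tokens, scale_of_token = scale_of,
       grid_position_of_token = pos,
       shapes = lapply(maps, function(m) c(h = m$h, w = m$w)))
}

#' Invert [flatten_concat()]
#' @param seq result of [flatten_concat()].
#' @return list of maps with `values`, `h`, `w`.
#' @export
unflatten <- function(seq) {
  out <- list()
  at <- 0L
  for (s in seq_along(seq$shapes)) {
    n <- seq$shapes[[s]]["h"] * seq$shapes[[s]]["w"]
    out[[s]] <- list(values = seq$tokens[(at + 1L):(at + n), , drop = FALSE],
                     h = unname(seq$shapes[[s]]["h"]),
                     w = unname(seq$shapes[[s]]["w"]), scale_id = s)
    at <- at + n
  }
  out
}
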