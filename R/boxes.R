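#' Bounding-box utilities
#'
#' Boxes are stored internally in normalized center form `(cx, cy, w, h)`,
#' each coordinate a fraction of the image side in `[0, 1]`. Conversion to
#' corner form `(x1, y1, x2, y2)` is exact. All functions are vectorized
#' over rows of an `n x 4` matrix.
#'
#' @param box numeric vector of length 4 or an `n x 4` matrix in
#'   `(cx, cy, w, h)` form.
#' @return `box_cxcywh_to_xyxy()` and `box_xyxy_to_cxcywh()` return a
#'   matrix of the same shape in the other parameterization.
#' @examples
#' box_cxcywh_to_xyxy(c(0.5, 0.5, 0.2, 0.4))
#' @export
box_cxcywh_to_xyxy <- function(box) {
  b <- as_box_matrix(box)
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' @rdname box_cxcywh_to_xyxy
#' @export
box_xyxy_to_cxcywh <- function(box) {
  b <- as_box_matrix(box)
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
        b[, 3] - b[, 1], b[, 4] - b[, 2])
}

as_box_matrix <- function(box) {
  if (is.null(dim(box))) box <- matrix(box, nrow = 1)
  if (ncol(box) != 4) stop("a box needs exactly 4 coordinates")
  box
}

validate_boxes <- function(box, what = "box") {
  b <- as_box_matrix(box)
  if (any(!is.finite(b))) stop(what, ": non-finite coordinate")
  if (any(b[, 3] <= 0) || any(b[, 4] <= 0))
    stop(what, ": zero- or negative-area box (w and h must be > 0)")
  invisible(b)
}

#' Intersection over union and generalized IoU
#'
#' `iou()` is the ratio of intersection to union area of two axis-aligned
#' boxes. `giou()` subtracts from the IoU the fraction of the smallest
#' enclosing box not covered by the union, extending the overlap measure to
#' disjoint boxes: it lies in `(-1, 1]` and equals the IoU when one box
#' contains the other.
#'
#' Both are vectorized: `a` and `b` may be `n x 4` matrices (paired rows).
#' Use [iou_matrix()] for all-pairs computation.
#'
#' @param a,b boxes in normalized `(cx, cy, w, h)` form; vectors of length 4
#'   or `n x 4` matrices.
#' @return numeric vector of length `n`.
#' @examples
#' a <- box_xyxy_to_cxcywh(c(0, 0, 2, 2))
#' b <- box_xyxy_to_cxcywh(c(1, 1, 3, 3))
#' iou(a, b)   # 1/7
#' giou(a, b)  # 1/7 - 2/9
#' @export
iou <- function(a, b) {
  pair_overlap(a, b)$iou
}

#' @rdname iou
#' @export
giou <- function(a, b) {
  ov <- pair_overlap(a, b)
  ov$iou - (ov$enclose - ov$union) / ov$enclose
}

pair_overlap <- function(a, b) {
  validate_boxes(a, "a"); validate_boxes(b, "b")
  A <- box_cxcywh_to_xyxy(a)
  B <- box_cxcywh_to_xyxy(b)
  if (nrow(A) != nrow(B)) {
    if (nrow(A) == 1) A <- A[rep(1, nrow(B)), , drop = FALSE]
    else if (nrow(B) == 1) B <- B[rep(1, nrow(A)), , drop = FALSE]
    else stop("a and b must have the same number of rows")
  }
  iw <- pmax(pmin(A[, 3], B[, 3]) - pmax(A[, 1], B[, 1]), 0)
  ih <- pmax(pmin(A[, 4], B[, 4]) - pmax(A[, 2], B[, 2]), 0)
  inter <- iw * ih
  area_a <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  area_b <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  union <- area_a + area_b - inter
  cw <- pmax(A[, 3], B[, 3]) - pmin(A[, 1], B[, 1])
  ch <- pmax(A[, 4], B[, 4]) - pmin(A[, 2], B[, 2])
  list(iou = inter / union, union = union, enclose = cw * ch)
}

#' All-pairs IoU between two box sets
#'
#' @param a `n x 4`, @param b `m x 4`, both `(cx, cy, w, h)`.
#' @return `n x m` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  ia <- rep(seq_len(n), times = m)
  ib <- rep(seq_len(m), each = n)
  matrix(iou(a[ia, , drop = FALSE], b[ib, , drop = FALSE]), n, m)
}

#' Clip a normalized box to the unit image
#'
#' Returns the clipped box in `(cx, cy, w, h)` form, or `NULL` when the
#' visible area falls below `min_area`.
#' @param box length-4 `(cx, cy, w, h)`.
#' @param min_area minimum surviving area (normalized units).
#' @export
clip_box <- function(box, min_area = 0) {
  xy <- box_cxcywh_to_xyxy(box)
  xy <- c(max(xy[1], 0), max(xy[2], 0), min(xy[3], 1), min(xy[4], 1))
  if (xy[3] - xy[1] <= 0 || xy[4] - xy[2] <= 0) return(NULL)
  if ((xy[3] - xy[1]) * (xy[4] - xy[2]) < min_area) return(NULL)
  drop(box_xyxy_to_cxcywh(xy))
}
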