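#' Loss weights and loss-related options
#'
#' @param lambda1 weight of the L1 box term.
#' @param lambda2 weight of the GIoU box term.
#' @param lambda3 weight of the classification terms (matching cost and
#'   cross-entropy).
#' @param lambda4 overall scale of the joint objective.
#' @param eos_coef down-weighting of the no-object class in the
#'   cross-entropy (with many more query slots than objects the no-object
#'   rows would otherwise dominate); set to 1 for the unweighted loss.
#' @param temperature softmax temperature of the contrastive loss.
#' @param giou_mode `"one_minus"` penalizes poor overlap with
#'   `1 - GIoU` (a proper loss); `"literal"` adds `+GIoU` instead and is
#'   kept only for audit -- minimizing it pushes boxes apart.
#' @param negatives `"all"` lets no-object-matched representations act as
#'   contrastive negatives; `"foreground"` restricts negatives to real
#'   classes.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 5, lambda2 = 2, lambda3 = 1, lambda4 = 1,
                         eos_coef = 0.1, temperature = 1,
                         giou_mode = c("one_minus", "literal"),
                         negatives = c("all", "foreground")) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, lambda4 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4, eos_coef = eos_coef,
                 temperature = temperature,
                 giou_mode = match.arg(giou_mode),
                 negatives = match.arg(negatives)),
            class = "loss_weights")
}

#' Box regression loss: weighted L1 plus GIoU term
#'
#' `lambda1 * |b_hat - b|_1 + lambda2 * (1 - GIoU(b_hat, b))` over the four
#' normalized cxcywh coordinates (vectorized over paired rows).
#'
#' @param bhat,b predicted and ground-truth boxes (`n x 4` or length 4).
#' @param w a [loss_weights()].
#' @export
box_loss <- function(bhat, b, w = loss_weights()) {
  bhat <- as_box_matrix(bhat); b <- as_box_matrix(b)
  l1 <- rowSums(abs(bhat - b))
  g <- giou(bhat, b)
  gterm <- if (w$giou_mode == "literal") g else 1 - g
  w$lambda1 * l1 + w$lambda2 * gterm
}

#' Matching cost of one prediction--ground-truth edge
#'
#' Box loss plus `lambda3 * (1 - p_hat(c))` where `p_hat(c)` is the
#' predicted probability of the ground-truth class.
#'
#' @param pred_probs length `C+1` probability vector of the prediction.
#' @param pred_box length-4 cxcywh box of the prediction.
#' @param gt_class 0-based foreground class of the ground-truth object.
#' @param gt_box its box.
#' @param w a [loss_weights()].
#' @export
matching_cost <- function(pred_probs, pred_box, gt_class, gt_box,
                          w = loss_weights()) {
  if (is.na(gt_class)) stop("matching cost is defined for real objects only")
  box_loss(pred_box, gt_box, w) + w$lambda3 * (1 - pred_probs[gt_class + 1L])
}

#' Pad ground truth to the query count
#'
#' Real objects first, then no-object padding (class `NA`).
#'
#' @param class_ids integer vector of 0-based classes (may be empty).
#' @param boxes `n x 4` cxcywh matrix (may have zero rows).
#' @param Q number of query slots; must be >= `n`.
#' @return list with `class_ids` (length `Q`, `NA` = no-object), `boxes`
#'   (`Q x 4`, `NA` rows for padding) and `n_real`.
#' @export
pad_ground_truth <- function(class_ids, boxes, Q) {
  n <- length(class_ids)
  if (n > Q) stop("more objects (", n, ") than query slots (", Q, ")")
  boxes <- if (n == 0) matrix(numeric(0), 0, 4) else as_box_matrix(boxes)
  list(class_ids = c(class_ids, rep(NA_integer_, Q - n)),
       boxes = rbind(boxes, matrix(NA_real_, Q - n, 4)),
       n_real = n)
}

#' Build the bipartite cost matrix
#'
#' Rows are (padded) ground-truth elements, columns are predictions. Real
#' rows hold [matching_cost()]; padded rows hold a constant 0, which leaves
#' the assignment of the real rows unchanged.
#'
#' @param gt a [pad_ground_truth()] result.
#' @param pred_probs `Q x (C+1)` probability matrix.
#' @param pred_boxes `Q x 4` cxcywh matrix.
#' @param w a [loss_weights()].
#' @return `Q x Q` numeric matrix.
#' @export
build_cost_matrix <- function(gt, pred_probs, pred_boxes, w = loss_weights()) {
  Q <- length(gt$class_ids)
  if (nrow(pred_probs) != Q || nrow(pred_boxes) != Q)
    stop("predictions and padded ground truth must both have ", Q, " elements")
  cm <- matrix(0, Q, Q)
  n <- gt$n_real
  if (n > 0) {
    for (i in seq_len(n)) {
      gtb <- matrix(gt$boxes[i, ], Q, 4, byrow = TRUE)
      cm[i, ] <- box_loss(pred_boxes, gtb, w) +
        w$lambda3 * (1 - pred_probs[, gt$class_ids[i] + 1L])
    }
  }
  cm
}

#' Match predictions to ground truth via the Hungarian algorithm
#'
#' @inheritParams build_cost_matrix
#' @return list with `h` (permutation: `h[i]` = prediction index matched to
#'   ground-truth row `i`), `total_cost`, and the cost matrix.
#' @export
match_predictions <- function(gt, pred_probs, pred_boxes, w = loss_weights()) {
  cm <- build_cost_matrix(gt, pred_probs, pred_boxes, w)
  res <- hungarian_match(cm)
  list(h = res$assignment, total_cost = res$total_cost, cost_matrix = cm)
}
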