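#' Average precision for one class at one IoU threshold
#'
#' Detections are ranked by descending score; each is greedily matched to
#' the unmatched same-class ground-truth box (in its image) of highest IoU,
#' and counts as a true positive when that IoU reaches the threshold. The
#' precision--recall curve is summarized by 101-point interpolation (mean
#' of the precision envelope at recalls 0, 0.01, ..., 1).
#'
#' @param dets data.frame with `image_id`, `class_id` (0-based), `score`,
#'   `cx`, `cy`, `w`, `h`.
#' @param gts list of scenes (ground truth), indexed by position =
#'   image_id.
#' @param class_id 0-based class to evaluate.
#' @param iou_threshold IoU needed for a true positive.
#' @param num_classes number of valid classes (for input checking).
#' @return AP in [0, 1], or `NA` when the class has no ground truth.
#' @export
average_precision <- function(dets, gts, class_id, iou_threshold,
                              num_classes = Inf) {
  if (class_id < 0 || class_id >= num_classes) stop("unknown class_id ", class_id)
  gt_boxes <- lapply(gts, function(sc) {
    cls <- scene_classes(sc)
    scene_boxes(sc)[cls == class_id, , drop = FALSE]
  })
  npos <- sum(vapply(gt_boxes, nrow, integer(1)))
  if (npos == 0) return(NA_real_)
  d <- dets[dets$class_id == class_id, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  d <- d[order(-d$score), , drop = FALSE]
  used <- lapply(gt_boxes, function(b) rep(FALSE, nrow(b)))
  tp <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    im <- d$image_id[i]
    gb <- gt_boxes[[im]]
    if (nrow(gb) == 0) next
    ious <- iou(matrix(c(d$cx[i], d$cy[i], d$w[i], d$h[i]), 1), gb)
    ious[used[[im]]] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      used[[im]][j] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / npos
  ap_101(precision, recall)
}

# 101-point interpolated AP: precision envelope sampled on a recall grid
ap_101 <- function(precision, recall) {
  env <- rev(cummax(rev(precision)))
  grid <- seq(0, 1, by = 0.01)
  idx <- findInterval(grid, recall, left.open = TRUE) + 1L
  p <- ifelse(idx <= length(env), env[idx], 0)
  mean(p)
}

#' COCO-style detection metrics
#'
#' Per-class AP at the ten IoU thresholds 0.50, 0.55, ..., 0.95; mAP values
#' are unweighted means over the classes present in the ground truth.
#'
#' @inheritParams average_precision
#' @param num_classes number of foreground classes.
#' @return an `ap_result` list: `per_class_ap` (class x threshold matrix),
#'   `map_per_threshold`, `map_all`, `map_50`, `map_75`.
#' @export
evaluate_detections <- function(dets, gts, num_classes) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  if (sum(vapply(gts, function(s) length(s$objects), integer(1))) == 0)
    stop("ground truth contains no objects")
  ap <- matrix(NA_real_, num_classes, length(thresholds),
               dimnames = list(paste0("class_", 0:(num_classes - 1)),
                               sprintf("iou_%.2f", thresholds)))
  for (cc in 0:(num_classes - 1))
    for (t in seq_along(thresholds))
      ap[cc + 1L, t] <- average_precision(dets, gts, cc, thresholds[t],
                                          num_classes)
  map_t <- colMeans(ap, na.rm = TRUE)
  structure(list(per_class_ap = ap,
                 map_per_threshold = map_t,
                 map_all = mean(map_t),
                 map_50 = unname(map_t[1]),
                 map_75 = unname(map_t[sprintf("iou_%.2f", 0.75)])),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("mAP@[0.5:0.05:0.95] %.4f | mAP50 %.4f | mAP75 %.4f\n",
              x$map_all, x$map_50, x$map_75))
  cat("per-class AP50:\n")
  print(round(x$per_class_ap[, 1], 4))
  invisible(x)
}

#' Embedding separability of object representations
#'
#' Quantifies how well the decoder's object representations cluster by
#' class: mean pairwise cosine similarity within classes and between
#' classes, plus the mean silhouette coefficient on cosine distance.
#'
#' @param reps `n x d` matrix of object representations.
#' @param labels length-`n` class labels (>= 2 distinct values).
#' @return list with `within_cos`, `between_cos`, `silhouette`.
#' @export
separability <- function(reps, labels) {
  n <- nrow(reps)
  if (n < 2) stop("need at least two representations")
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2) stop("need at least two classes")
  norms <- sqrt(rowSums(reps * reps))
  xn <- reps / norms
  S <- tcrossprod(xn)
  same <- outer(labels, labels, "==")
  off <- !diag(n)
  within <- mean(S[same & off])
  between <- mean(S[!same])
  D <- 1 - S
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else NA
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    sil[i] <- if (is.na(a)) 0 else (b - a) / max(a, b)
  }
  list(within_cos = within, between_cos = between, silhouette = mean(sil))
}
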