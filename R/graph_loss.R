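# Differentiable (tape) versions of the training losses. The bipartite
# matching itself is solved numerically on detached values -- the assignment
# is piecewise constant in the parameters -- and the loss graph is then
# built on the matched rows. Numeric equivalence with the public
# hungarian_loss()/contrastive_loss() is asserted in the test suite.

col_of <- function(x, j) ad_cols(x, j)

# GIoU of paired rows, as a graph; pb node (n x 4 cxcywh), gt constant matrix
giou_graph <- function(pb, gt) {
  gx <- box_cxcywh_to_xyxy(gt)
  half_w <- ad_scale(col_of(pb, 3L), 0.5)
  half_h <- ad_scale(col_of(pb, 4L), 0.5)
  px1 <- ad_sub(col_of(pb, 1L), half_w); px2 <- ad_add(col_of(pb, 1L), half_w)
  py1 <- ad_sub(col_of(pb, 2L), half_h); py2 <- ad_add(col_of(pb, 2L), half_h)
  cx1 <- ad_const(matrix(gx[, 1], ncol = 1)); cy1 <- ad_const(matrix(gx[, 2], ncol = 1))
  cx2 <- ad_const(matrix(gx[, 3], ncol = 1)); cy2 <- ad_const(matrix(gx[, 4], ncol = 1))
  iw <- ad_pmax_const(ad_sub(ad_pmin2(px2, cx2), ad_pmax2(px1, cx1)), 0)
  ih <- ad_pmax_const(ad_sub(ad_pmin2(py2, cy2), ad_pmax2(py1, cy1)), 0)
  inter <- ad_mul(iw, ih)
  area_p <- ad_mul(col_of(pb, 3L), col_of(pb, 4L))
  area_g <- ad_const(matrix((gx[, 3] - gx[, 1]) * (gx[, 4] - gx[, 2]), ncol = 1))
  union <- ad_pmax_const(ad_sub(ad_add(area_p, area_g), inter), 1e-12)
  cw <- ad_sub(ad_pmax2(px2, cx2), ad_pmin2(px1, cx1))
  ch <- ad_sub(ad_pmax2(py2, cy2), ad_pmin2(py1, cy1))
  enclose <- ad_pmax_const(ad_mul(cw, ch), 1e-12)
  # iou - (enclose - union)/enclose = iou - 1 + union/enclose
  iou_n <- ad_mul(inter, ad_recip(union))
  ad_add_const(ad_add(iou_n, ad_mul(union, ad_recip(enclose))), -1)
}

# Hungarian loss as a graph for one image. Returns list(node, h, gt).
hungarian_loss_graph <- function(out, class_ids, gt_boxes, w, Q) {
  probs <- softmax_rows(out$logits$val)
  gt <- pad_ground_truth(class_ids, gt_boxes, Q)
  h <- match_predictions(gt, probs, out$boxes$val, w)$h
  C1 <- ncol(out$logits$val)
  target_col <- ifelse(is.na(gt$class_ids), C1, gt$class_ids + 1L)
  alpha <- ifelse(is.na(gt$class_ids), w$eos_coef, 1)
  logp <- ad_log(ad_pmax_const(ad_softmax_rows(out$logits), 1e-12))
  pick <- ad_gather(logp, cbind(h, target_col))
  node <- ad_scale(ad_sum(ad_mul(pick, ad_const(matrix(alpha, ncol = 1)))), -w$lambda3)
  n <- gt$n_real
  if (n > 0) {
    pb <- ad_rows(out$boxes, h[seq_len(n)])
    gtb <- gt$boxes[seq_len(n), , drop = FALSE]
    l1 <- ad_sum(ad_abs(ad_sub(pb, ad_const(gtb))))
    g <- giou_graph(pb, gtb)
    gterm <- if (w$giou_mode == "literal") ad_sum(g)
             else ad_sum(ad_scale(ad_add_const(g, -1), -1))
    node <- ad_add(node, ad_add(ad_scale(l1, w$lambda1), ad_scale(gterm, w$lambda2)))
  }
  list(node = node, h = h, gt = gt)
}

# Contrastive loss graph over matched representations of the whole batch.
# items: list of list(reps = node Q x d, h, gt). Returns scalar node (or NULL
# when no foreground class is present).
contrastive_loss_graph <- function(items, w) {
  matched <- lapply(items, function(it) ad_rows(it$reps, it$h))
  labels <- unlist(lapply(items, function(it) {
    ifelse(is.na(it$gt$class_ids), -1L, it$gt$class_ids)
  }))
  allr <- if (length(matched) > 1L) ad_rbind(matched) else matched[[1]]
  rs <- ad_rowsums(ad_mul(allr, allr))
  inv_norm <- ad_recip(ad_sqrt(ad_add_const(rs, 1e-12)))
  xn <- ad_scale_rows(allr, inv_norm)
  S <- ad_matmul(xn, xn, tb = TRUE)
  present <- sort(unique(labels[labels >= 0L]))
  if (length(present) == 0) return(NULL)
  per_class <- vector("list", length(present))
  for (k in seq_along(present)) {
    cc <- present[k]
    gp <- which(labels == cc)
    gn <- if (w$negatives == "all") which(labels != cc) else
      which(labels != cc & labels >= 0L)
    m <- length(gp)
    Pij <- if (m >= 2) {
      ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      cbind(gp[ij[, 1]], gp[ij[, 2]])
    } else cbind(gp, gp)
    num <- ad_sum(ad_exp(ad_scale(ad_gather(S, Pij), 1 / w$temperature)))
    den <- num
    if (length(gn) > 0) {
      Nij <- cbind(rep(gp, each = length(gn)), rep(gn, times = m))
      den <- ad_add(den, ad_sum(ad_exp(ad_scale(ad_gather(S, Nij), 1 / w$temperature))))
    }
    per_class[[k]] <- ad_sub(ad_log(den), ad_log(num))
  }
  ad_scale(Reduce(ad_add, per_class), 1 / length(present))
}

# Joint objective for a batch of scenes. Returns the loss node plus numeric
# diagnostics; forward passes share one tape with the caller.
batch_loss_graph <- function(P, config, scenes, w, contrastive = TRUE) {
  Q <- config$num_queries
  items <- vector("list", length(scenes))
  lh_nodes <- vector("list", length(scenes))
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    mat <- sc$.mat %||% image_to_matrix(sc$image)
    out <- detector_fwd(P, config, mat, dim(sc$image)[1], dim(sc$image)[2])
    hl <- hungarian_loss_graph(out, scene_classes(sc), scene_boxes(sc), w, Q)
    lh_nodes[[k]] <- hl$node
    items[[k]] <- list(reps = out$reps, h = hl$h, gt = hl$gt)
  }
  lh_sum <- Reduce(ad_add, lh_nodes)
  node <- ad_scale(lh_sum, w$lambda4 / length(scenes))
  lcl_val <- 0
  if (contrastive) {
    lcl <- contrastive_loss_graph(items, w)
    if (!is.null(lcl)) {
      node <- ad_add(node, ad_scale(lcl, w$lambda4))
      lcl_val <- as.numeric(lcl$val)
    }
  }
  list(node = node,
       hungarian = as.numeric(lh_sum$val) / length(scenes),
       contrastive = lcl_val,
       total = as.numeric(node$val))
}

scene_classes <- function(scene) {
  if (length(scene$objects) == 0) integer(0)
  else vapply(scene$objects, function(o) as.integer(o$class_id), integer(1))
}

scene_boxes <- function(scene) {
  if (length(scene$objects) == 0) matrix(numeric(0), 0, 4)
  else do.call(rbind, lapply(scene$objects, function(o) o$box))
}
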