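#' Hungarian set-prediction loss
#'
#' Given the optimal assignment `h`, sums over all ground-truth rows the
#' cross-entropy of the matched prediction against the row's class (the
#' no-object class for padding rows, down-weighted by `eos_coef`) plus, for
#' real rows only, the box loss of the matched box.
#'
#' @param gt a [pad_ground_truth()] result.
#' @param pred_probs `Q x (C+1)` probability matrix (column `C+1` is the
#'   no-object class).
#' @param pred_boxes `Q x 4` cxcywh matrix.
#' @param h assignment from [match_predictions()].
#' @param w a [loss_weights()].
#' @return nonnegative scalar.
#' @export
hungarian_loss <- function(gt, pred_probs, pred_boxes, h, w = loss_weights()) {
  Q <- length(gt$class_ids)
  C1 <- ncol(pred_probs)
  target_col <- ifelse(is.na(gt$class_ids), C1, gt$class_ids + 1L)
  p <- pmax(pred_probs[cbind(h, target_col)], 1e-12)
  alpha <- ifelse(is.na(gt$class_ids), w$eos_coef, 1)
  ce <- -w$lambda3 * sum(alpha * log(p))
  n <- gt$n_real
  bx <- if (n > 0) {
    sum(box_loss(pred_boxes[h[seq_len(n)], , drop = FALSE],
                 gt$boxes[seq_len(n), , drop = FALSE], w))
  } else 0
  ce + bx
}

#' Contrastive pairs for one class from a matched batch
#'
#' Walks every sample's (padded) ground-truth rows and collects the matched
#' object representations: rows of class `c` become positive samples,
#' everything else (including no-object rows when `negatives = "all"`)
#' becomes negative samples. Positive pairs are all unordered pairs of
#' positives; a lone positive is paired with itself so it is still pushed
#' away from the negatives. Negative pairs couple every positive with every
#' negative.
#'
#' @param batch list of samples, each a list with `gt`
#'   ([pad_ground_truth()]), `reps` (`Q x d` object representations) and
#'   `h` (assignment).
#' @param class_id 0-based foreground class; must occur in the batch.
#' @param w a [loss_weights()] (controls the negative set).
#' @return list with `pos` (`m x d`), `neg` (`q x d`), `P` (index pairs into
#'   `pos`), `N` (index pairs: positive index, negative index).
#' @export
build_contrastive_pairs <- function(batch, class_id, w = loss_weights()) {
  pos <- list(); neg <- list()
  for (sample in batch) {
    matched <- sample$reps[sample$h, , drop = FALSE]
    for (i in seq_along(sample$gt$class_ids)) {
      ci <- sample$gt$class_ids[i]
      if (!is.na(ci) && ci == class_id) {
        pos[[length(pos) + 1L]] <- matched[i, ]
      } else if (!is.na(ci) || w$negatives == "all") {
        neg[[length(neg) + 1L]] <- matched[i, ]
      }
    }
  }
  m <- length(pos)
  if (m == 0) stop("class ", class_id, " has no matched objects in the batch")
  q <- length(neg)
  P <- matrix(integer(0), 0, 2)
  N <- matrix(integer(0), 0, 2)
  if (q > 0) N <- cbind(rep(seq_len(m), each = q), rep(seq_len(q), times = m))
  if (m >= 2) {
    ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    P <- cbind(ij[, "row"], ij[, "col"])
  } else {
    P <- matrix(c(1L, 1L), 1, 2)
  }
  list(pos = do.call(rbind, pos),
       neg = if (q > 0) do.call(rbind, neg) else matrix(numeric(0), 0, length(pos[[1]])),
       P = unname(P), N = unname(N))
}

cosine_sim_pairs <- function(a, b) {
  na <- sqrt(rowSums(a * a)); nb <- sqrt(rowSums(b * b))
  if (any(na == 0) || any(nb == 0)) stop("zero-norm object representation")
  rowSums(a * b) / (na * nb)
}

#' Per-class contrastive loss
#'
#' Normalized-temperature cross-entropy over the positive pairs against the
#' pooled positive and negative pairs, with cosine similarity:
#' `-log( sum_P exp(sim/tau) / sum_{P u N} exp(sim/tau) )`. Zero when there
#' are no negative pairs; strictly positive otherwise.
#'
#' @param pairs result of [build_contrastive_pairs()].
#' @param temperature softmax temperature `tau`.
#' @export
contrastive_loss_class <- function(pairs, temperature = 1) {
  sp <- cosine_sim_pairs(pairs$pos[pairs$P[, 1], , drop = FALSE],
                         pairs$pos[pairs$P[, 2], , drop = FALSE])
  num <- sum(exp(sp / temperature))
  den <- num
  if (nrow(pairs$N) > 0) {
    sn <- cosine_sim_pairs(pairs$pos[pairs$N[, 1], , drop = FALSE],
                           pairs$neg[pairs$N[, 2], , drop = FALSE])
    den <- den + sum(exp(sn / temperature))
  }
  -log(num / den)
}

#' Batch contrastive loss
#'
#' Mean of [contrastive_loss_class()] over the foreground classes present
#' in the batch ground truth; 0 for a batch with no real objects.
#'
#' @inheritParams build_contrastive_pairs
#' @param w a [loss_weights()].
#' @export
contrastive_loss <- function(batch, w = loss_weights()) {
  present <- present_classes(batch)
  if (length(present) == 0) return(0)
  mean(vapply(present, function(cc)
    contrastive_loss_class(build_contrastive_pairs(batch, cc, w), w$temperature),
    numeric(1)))
}

present_classes <- function(batch) {
  sort(unique(unlist(lapply(batch, function(s)
    s$gt$class_ids[!is.na(s$gt$class_ids)]))))
}

#' Joint training objective
#'
#' `lambda4/bs * sum_k L_Hungarian(k) + lambda4/nc * sum_c L_contrastive(c)`
#' over a matched batch. Set `contrastive = FALSE` for the
#' set-prediction-only ablation objective.
#'
#' @param batch list of samples, each with `gt`, `pred_probs`, `pred_boxes`,
#'   `reps`, `h`.
#' @param w a [loss_weights()].
#' @param contrastive include the contrastive term.
#' @return list with `total`, `hungarian`, `contrastive`.
#' @export
total_loss <- function(batch, w = loss_weights(), contrastive = TRUE) {
  bs <- length(batch)
  lh <- vapply(batch, function(s)
    hungarian_loss(s$gt, s$pred_probs, s$pred_boxes, s$h, w), numeric(1))
  lcl <- 0
  if (contrastive) {
    present <- present_classes(batch)
    if (length(present) > 0) {
      per_class <- vapply(present, function(cc)
        contrastive_loss_class(build_contrastive_pairs(batch, cc, w),
                               w$temperature), numeric(1))
      lcl <- mean(per_class)
    }
  }
  list(total = w$lambda4 * (sum(lh) / bs + lcl),
       hungarian = sum(lh) / bs, contrastive = lcl)
}
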