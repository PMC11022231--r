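#' Training configuration
#'
#' Optimization schedule defaults: AdamW starting at 1e-4 with a step decay
#' of 0.5 every 40 epochs down to a floor of 1e-6, early stopping on the
#' validation loss with patience 50 and minimum delta 1e-5. Desk-scale runs
#' on the tiny model typically override `learning_rate` upward (see the
#' methods vignette) since they train for tens, not hundreds, of epochs.
#'
#' @param epochs maximum training epochs.
#' @param batch_size scenes per optimization step.
#' @param learning_rate,lr_floor,lr_decay,lr_interval step-schedule
#'   parameters: rate at epoch `e` (0-based) is
#'   `learning_rate * lr_decay^(e %/% lr_interval)`, clipped at `lr_floor`.
#' @param patience,min_delta early stopping: stop when the best validation
#'   loss has not improved by more than `min_delta` for `patience` epochs.
#' @param val_fraction held-out fraction of the scenes.
#' @param augment,augment_p apply the geometric augmentation during
#'   training, each transform with probability `augment_p`.
#' @param clip_norm global gradient-norm clip (0 disables).
#' @param weight_decay AdamW decoupled weight decay.
#' @param contrastive include the contrastive term in the objective.
#' @param seed seed controlling the split, shuffling and augmentation.
#' @param log_file optional JSON-lines file receiving one record per epoch.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L,
                         learning_rate = 1e-4, lr_floor = 1e-6,
                         lr_decay = 0.5, lr_interval = 40L,
                         patience = 50L, min_delta = 1e-5,
                         val_fraction = 0.3, augment = TRUE, augment_p = 1 / 3,
                         clip_norm = 0.1, weight_decay = 1e-4,
                         contrastive = TRUE, seed = 1L, log_file = NULL) {
  if (lr_floor >= learning_rate) stop("lr_floor must be below learning_rate")
  if (patience < 1) stop("patience must be >= 1")
  structure(as.list(environment()), class = "train_config")
}

#' Learning rate at a (0-based) epoch under the step schedule
#' @param e epoch index, 0-based.
#' @param cfg a [train_config()].
#' @export
lr_at_epoch <- function(e, cfg = train_config()) {
  max(cfg$learning_rate * cfg$lr_decay^(e %/% cfg$lr_interval), cfg$lr_floor)
}

#' Early-stopping decision from a validation-loss history
#'
#' TRUE when the best loss seen so far has not been beaten by strictly more
#' than `min_delta` for `patience` consecutive epochs.
#' @param history numeric vector of validation losses, oldest first.
#' @param cfg a [train_config()].
#' @export
early_stop <- function(history, cfg = train_config()) {
  if (length(history) == 0) stop("history must be non-empty")
  best <- history[1]
  since <- 0L
  for (v in history[-1]) {
    if (v < best - cfg$min_delta) {
      best <- v
      since <- 0L
    } else {
      since <- since + 1L
    }
  }
  since >= cfg$patience
}

#' Fit the set-prediction tool detector
#'
#' Trains the transformer detector on a list of annotated scenes by
#' minimizing the joint objective: the Hungarian set loss (cross-entropy
#' plus L1/GIoU box terms on the optimal bipartite assignment) plus, when
#' enabled, the supervised contrastive loss over matched object
#' representations. Optimization is AdamW with a step learning-rate
#' schedule, gradient clipping and early stopping on the validation loss;
#' the returned model carries the parameters of the best validation epoch.
#'
#' @param scenes list of scenes (`image`, `objects`), e.g. from
#'   [generate_scenes()] or [read_coco()].
#' @param config a [detector_config()]; defaults to the desk-scale tiny
#'   model sized for the training images.
#' @param weights a [loss_weights()].
#' @param train a [train_config()].
#' @param verbose print one line per epoch.
#' @return an object of class `tooldetr`.
#' @examples
#' \donttest{
#' cfg <- generator_config(num_classes = 3, seed = 7)
#' scenes <- generate_scenes(cfg, 24)
#' fit <- tooldetr(scenes, tiny_detector_config(num_classes = 3),
#'                 train = train_config(epochs = 2, learning_rate = 1e-3,
#'                                      augment = FALSE, seed = 7))
#' print(fit)
#' }
#' @export
tooldetr <- function(scenes, config = NULL, weights = loss_weights(),
                     train = train_config(), verbose = interactive()) {
  if (length(scenes) < 2) stop("need at least two scenes")
  if (is.null(config)) {
    ncls <- max(c(0L, unlist(lapply(scenes, scene_classes)))) + 1L
    config <- tiny_detector_config(num_classes = max(ncls, 2L))
  }
  nmax <- max(vapply(scenes, function(s) length(s$objects), integer(1)))
  if (config$num_queries < nmax)
    stop("num_queries (", config$num_queries, ") below max objects per scene (",
         nmax, ")")
  set.seed(train$seed)
  n <- length(scenes)
  val_idx <- sort(sample(n, max(1, round(train$val_fraction * n))))
  train_idx <- setdiff(seq_len(n), val_idx)
  val_scenes <- lapply(scenes[val_idx], with_mat)
  base_train <- scenes[train_idx]

  params <- detector_init(config, seed = train$seed)
  opt <- adamw_init(params)
  history <- list()
  best_val <- Inf
  best_params <- params
  log_con <- if (!is.null(train$log_file)) file(train$log_file, open = "wt")
  on.exit(if (!is.null(log_con)) close(log_con), add = TRUE)

  for (epoch in seq_len(train$epochs) - 1L) {
    lr <- lr_at_epoch(epoch, train)
    ep_scenes <- if (train$augment) {
      lapply(base_train, function(s) with_mat(augment(s, p = train$augment_p)))
    } else {
      lapply(base_train, with_mat)
    }
    ord <- sample(length(ep_scenes))
    batches <- split(ord, ceiling(seq_along(ord) / train$batch_size))
    tr_loss <- 0; tr_h <- 0; tr_c <- 0
    for (b in batches) {
      tape <- ad_tape_begin()
      Pn <- wrap_params(params)
      bl <- tryCatch(batch_loss_graph(Pn, config, ep_scenes[b], weights,
                                      contrastive = train$contrastive),
                     error = function(e) { ad_tape_end(); stop(e) })
      if (!is.finite(bl$total))
        stop("non-finite loss at epoch ", epoch, " (hungarian = ", bl$hungarian,
             ", contrastive = ", bl$contrastive, ")")
      ad_backward(tape, bl$node)
      ad_tape_end()
      upd <- adamw_step(params, collect_grads(Pn), opt, lr,
                        weight_decay = train$weight_decay,
                        clip_norm = train$clip_norm)
      params <- upd$params
      opt <- upd$state
      tr_loss <- tr_loss + bl$total * length(b)
      tr_h <- tr_h + bl$hungarian * length(b)
      tr_c <- tr_c + bl$contrastive * length(b)
    }
    ntr <- length(ep_scenes)
    val_loss <- validation_loss(params, config, val_scenes, weights, train)
    rec <- list(epoch = epoch, lr = lr, train_loss = tr_loss / ntr,
                train_hungarian = tr_h / ntr, train_contrastive = tr_c / ntr,
                val_loss = val_loss)
    history[[length(history) + 1L]] <- rec
    if (!is.null(log_con))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), log_con)
    if (verbose)
      message(sprintf("epoch %3d lr %.2e train %.4f val %.4f",
                      epoch, lr, rec$train_loss, val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
    }
    if (early_stop(vapply(history, `[[`, numeric(1), "val_loss"), train)) break
  }

  structure(list(params = best_params, last_params = params, config = config,
                 weights = weights, train = train,
                 history = do.call(rbind, lapply(history, as.data.frame)),
                 best_val = best_val,
                 n_train = length(train_idx), n_val = length(val_idx),
                 val_idx = val_idx),
            class = "tooldetr")
}

with_mat <- function(scene) {
  scene$.mat <- image_to_matrix(scene$image)
  scene
}

validation_loss <- function(params, config, scenes, weights, train) {
  P <- lapply(params, ad_const)
  batches <- split(seq_along(scenes), ceiling(seq_along(scenes) / train$batch_size))
  tot <- 0
  for (b in batches) {
    bl <- batch_loss_graph(P, config, scenes[b], weights,
                           contrastive = train$contrastive)
    tot <- tot + bl$total * length(b)
  }
  tot / length(scenes)
}

#' @export
print.tooldetr <- function(x, ...) {
  cat("Set-prediction tool detector (", x$config$backbone$variant,
      " backbone, d = ", x$config$embed_dim, ", Q = ", x$config$num_queries,
      ")\n", sep = "")
  cat(sprintf("  trained %d epochs on %d scenes (%d held out); best val loss %.4f\n",
              nrow(x$history), x$n_train + x$n_val, x$n_val, x$best_val))
  invisible(x)
}

#' @export
summary.tooldetr <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  train loss %.4f -> %.4f (hungarian %.4f, contrastive %.4f)\n",
              h$train_loss[1], h$train_loss[nrow(h)],
              h$train_hungarian[nrow(h)], h$train_contrastive[nrow(h)]))
  cat(sprintf("  %d parameters in %d tensors\n",
              sum(vapply(object$params, length, numeric(1))),
              length(object$params)))
  invisible(object)
}

#' @export
coef.tooldetr <- function(object, ...) object$params

#' @export
plot.tooldetr <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Detect objects in new scenes
#'
#' @param object a fitted `tooldetr` model.
#' @param newdata list of scenes (only `image` is used).
#' @param score_threshold foreground probability cutoff (defaults to the
#'   model config).
#' @param ... unused.
#' @return data.frame of detections: `image_id`, `class_id` (0-based),
#'   `score`, `cx`, `cy`, `w`, `h`.
#' @export
predict.tooldetr <- function(object, newdata, score_threshold = NULL, ...) {
  thr <- score_threshold %||% object$config$score_threshold
  out <- lapply(seq_along(newdata), function(i) {
    fw <- detector_forward(object$params, object$config, newdata[[i]]$image)
    d <- postprocess(fw$class_probs, fw$boxes, thr)
    if (nrow(d) > 0) cbind(image_id = i, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(image_id = integer(0), class_id = integer(0),
                      score = numeric(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  out
}

#' Matched object representations on annotated scenes
#'
#' Runs the detector, solves the bipartite matching against the scene
#' annotations, and returns the decoder representations assigned to the
#' real objects together with their ground-truth labels -- the raw material
#' of the embedding-separability analysis.
#'
#' @param object a fitted `tooldetr` model.
#' @param scenes annotated scenes.
#' @return list with `reps` (n x d matrix) and `labels`.
#' @export
matched_representations <- function(object, scenes) {
  reps <- list(); labels <- integer(0)
  for (sc in scenes) {
    cls <- scene_classes(sc)
    if (length(cls) == 0) next
    fw <- detector_forward(object$params, object$config, sc$image)
    gt <- pad_ground_truth(cls, scene_boxes(sc), object$config$num_queries)
    h <- match_predictions(gt, fw$class_probs, fw$boxes, object$weights)$h
    reps[[length(reps) + 1L]] <- fw$reps[h[seq_along(cls)], , drop = FALSE]
    labels <- c(labels, cls)
  }
  list(reps = do.call(rbind, reps), labels = labels)
}

#' Evaluate a fitted detector on annotated scenes
#'
#' Average precision is computed over *all* query predictions: every query
#' contributes a detection for its most probable foreground class, scored by
#' that class probability, and the ranking absorbs low-confidence outputs
#' naturally (no score-threshold filtering inside evaluation). Use
#' [predict.tooldetr()] / [postprocess()] for thresholded inference output.
#'
#' @param object a fitted `tooldetr` model.
#' @param scenes annotated scenes.
#' @return an `ap_result` (see [evaluate_detections()]).
#' @export
evaluate_model <- function(object, scenes) {
  C <- object$config$num_classes
  out <- lapply(seq_along(scenes), function(i) {
    fw <- detector_forward(object$params, object$config, scenes[[i]]$image)
    fg <- fw$class_probs[, seq_len(C), drop = FALSE]
    cls <- max.col(fg, ties.method = "first")
    data.frame(image_id = i, class_id = cls - 1L,
               score = fg[cbind(seq_len(nrow(fg)), cls)],
               cx = fw$boxes[, 1], cy = fw$boxes[, 2],
               w = fw$boxes[, 3], h = fw$boxes[, 4])
  })
  evaluate_detections(do.call(rbind, out), scenes, C)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding parameters, configuration and training
#' history.
#' @param object a `tooldetr` model; `path` file path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "tooldetr")) stop("not a tooldetr checkpoint: ", path)
  obj
}
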