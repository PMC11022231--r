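# Independent brute-force implementations used as oracles: a literal,
# loop-based transcription of the set loss and of the pair-building
# algorithm, kept free of any package internals.

oracle_hungarian_loss <- function(gt, probs, boxes, h, w) {
  total <- 0
  for (i in seq_along(gt$class_ids)) {
    ci <- gt$class_ids[i]
    j <- h[i]
    if (is.na(ci)) {
      total <- total - w$lambda3 * w$eos_coef * log(max(probs[j, ncol(probs)], 1e-12))
    } else {
      total <- total - w$lambda3 * log(max(probs[j, ci + 1], 1e-12))
      l1 <- sum(abs(boxes[j, ] - gt$boxes[i, ]))
      total <- total + w$lambda1 * l1 + w$lambda2 * (1 - giou(boxes[j, ], gt$boxes[i, ]))
    }
  }
  total
}

oracle_pairs <- function(batch, cc) {
  pos <- list(); neg <- list()
  for (k in seq_along(batch)) {
    s <- batch[[k]]
    for (i in seq_along(s$gt$class_ids)) {
      o <- s$reps[s$h[i], ]
      if (!is.na(s$gt$class_ids[i]) && s$gt$class_ids[i] == cc)
        pos[[length(pos) + 1]] <- o
      else
        neg[[length(neg) + 1]] <- o
    }
  }
  P <- list(); N <- list()
  while (length(pos) > 0) {
    o <- pos[[1]]
    for (op in neg) N[[length(N) + 1]] <- list(o, op)
    pos[[1]] <- NULL                     # progressive removal
    for (op in pos) P[[length(P) + 1]] <- list(o, op)
    if (length(P) == 0) P[[1]] <- list(o, o)
  }
  list(P = P, N = N)
}

oracle_contrastive_class <- function(pr, tau = 1) {
  cs <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  num <- sum(vapply(pr$P, function(p) exp(cs(p[[1]], p[[2]]) / tau), numeric(1)))
  den <- num + sum(vapply(pr$N, function(p) exp(cs(p[[1]], p[[2]]) / tau), numeric(1)))
  -log(num / den)
}

test_that("hungarian loss reproduces hand-computed values", {
  w <- loss_weights(lambda3 = 1, eos_coef = 1)
  b <- c(0.5, 0.5, 0.2, 0.2)
  # perfect prediction: zero loss
  gt <- pad_ground_truth(0L, matrix(b, 1), 2L)
  probs <- rbind(c(1, 0, 0), c(0, 0, 1))
  boxes <- rbind(b, b)
  expect_equal(hungarian_loss(gt, probs, boxes, c(1L, 2L), w), 0)
  # p(target) = exp(-1) on one real object, exact box: loss 1
  probs2 <- rbind(c(exp(-1), 1 - exp(-1), 0), c(0, 0, 1))
  expect_equal(hungarian_loss(gt, probs2, boxes, c(1L, 2L), w), 1)
  # padded rows contribute no box term whatever the predicted boxes
  boxes_wild <- rbind(b, c(0.9, 0.9, 0.05, 0.05))
  expect_equal(hungarian_loss(gt, probs, boxes_wild, c(1L, 2L), w), 0)
  # down-weighting scales only the no-object rows
  w2 <- loss_weights(eos_coef = 0.1)
  probs3 <- rbind(c(1, 0, 0), c(0, 0, 0.5))
  expect_equal(hungarian_loss(gt, probs3, boxes, c(1L, 2L), w2),
               -0.1 * log(0.5))
})

test_that("degenerate probabilities stay finite through the clamped log", {
  gt <- pad_ground_truth(0L, matrix(c(0.5, 0.5, 0.2, 0.2), 1), 1L)
  probs <- matrix(c(0, 1, 0), 1)
  l <- hungarian_loss(gt, probs, matrix(c(0.5, 0.5, 0.2, 0.2), 1), 1L,
                      loss_weights())
  expect_true(is.finite(l))
})

test_that("pair accounting matches the combinatorial formulae", {
  set.seed(2)
  d <- 4
  for (m in 1:6) for (q in 0:6) {
    # one sample whose first m rows are class 0, next q rows class 1
    Q <- m + q
    gt <- pad_ground_truth(c(rep(0L, m), rep(1L, q)),
                           random_box(Q), Q)
    sample1 <- list(gt = gt, reps = matrix(rnorm(Q * d), Q, d), h = seq_len(Q))
    pr <- build_contrastive_pairs(list(sample1), 0L)
    expect_equal(nrow(pr$P), if (m >= 2) m * (m - 1) / 2 else 1)
    expect_equal(nrow(pr$N), m * q)
    if (m == 1) expect_equal(pr$P, matrix(c(1L, 1L), 1, 2))
    # no duplicated unordered positive pairs
    if (m >= 2) {
      key <- paste(pmin(pr$P[, 1], pr$P[, 2]), pmax(pr$P[, 1], pr$P[, 2]))
      expect_equal(anyDuplicated(key), 0L)
    }
  }
  expect_error(build_contrastive_pairs(list(sample1), 5L), "no matched objects")
})

test_that("hand-enumerated example: 3 positives, 4 other rows", {
  set.seed(3)
  gt <- pad_ground_truth(c(2L, 2L, 2L, 0L, 1L), random_box(5), 7L)
  s <- list(gt = gt, reps = matrix(rnorm(7 * 5), 7, 5), h = sample(7))
  pr <- build_contrastive_pairs(list(s), 2L)
  expect_equal(nrow(pr$P), 3)   # (o1,o2), (o1,o3), (o2,o3)
  expect_equal(nrow(pr$N), 12)  # 3 positives x 4 negatives (2 real + 2 padded)
})

test_that("contrastive loss reproduces the direct substitution example", {
  # P = {(o,o)} with sim 1; N = one pair with sim 0
  o <- c(1, 0)
  pr <- list(pos = matrix(o, 1, 2, byrow = TRUE),
             neg = matrix(c(0, 1), 1, 2, byrow = TRUE),
             P = matrix(c(1L, 1L), 1, 2), N = matrix(c(1L, 1L), 1, 2))
  expect_equal(contrastive_loss_class(pr, temperature = 1),
               -log(exp(1) / (exp(1) + 1)))
  # no negatives: ratio 1, loss 0
  pr0 <- list(pos = pr$pos, neg = pr$neg[0, , drop = FALSE],
              P = pr$P, N = matrix(integer(0), 0, 2))
  expect_equal(contrastive_loss_class(pr0), 0)
  expect_error(contrastive_loss_class(list(pos = matrix(0, 1, 2),
                                           neg = pr$neg, P = pr$P, N = pr$N)),
               "zero-norm")
})

test_that("losses agree with independent brute-force oracles on random batches", {
  set.seed(11)
  w <- loss_weights()
  for (t in 1:60) {
    batch <- random_batch(bs = sample(1:3, 1), Q = sample(2:6, 1), C = 3)
    for (s in batch)
      expect_equal(hungarian_loss(s$gt, s$pred_probs, s$pred_boxes, s$h, w),
                   oracle_hungarian_loss(s$gt, s$pred_probs, s$pred_boxes, s$h, w),
                   tolerance = 1e-9)
    present <- sort(unique(unlist(lapply(batch, function(s)
      s$gt$class_ids[!is.na(s$gt$class_ids)]))))
    if (length(present) > 0) {
      ours <- contrastive_loss(batch, w)
      ref <- mean(vapply(present, function(cc)
        oracle_contrastive_class(oracle_pairs(batch, cc)), numeric(1)))
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  }
})

test_that("clustered embeddings score lower than label-permuted ones", {
  set.seed(4)
  centers <- diag(3) * 4
  mk <- function(lbls) {
    Q <- length(lbls)
    gt <- pad_ground_truth(lbls, random_box(Q), Q)
    reps <- centers[lbls + 1, ] + matrix(rnorm(Q * 3, sd = 0.05), Q, 3)
    list(gt = gt, reps = reps, h = seq_len(Q),
         pred_probs = random_probs(Q, 4), pred_boxes = random_box(Q))
  }
  lbls <- c(0L, 0L, 1L, 1L, 2L, 2L)
  clustered <- list(mk(lbls))
  worse <- 0
  for (t in 1:20) {
    perm_batch <- list(mk(sample(lbls)))
    perm_batch[[1]]$reps <- clustered[[1]]$reps
    if (contrastive_loss(perm_batch) >= contrastive_loss(clustered)) worse <- worse + 1
  }
  expect_gte(worse, 19)
})

test_that("total loss combines the terms with the documented scaling", {
  set.seed(6)
  batch <- random_batch(2, 4, 3)
  w <- loss_weights(lambda4 = 1)
  tl <- total_loss(batch, w)
  lh <- mean(vapply(batch, function(s)
    hungarian_loss(s$gt, s$pred_probs, s$pred_boxes, s$h, w), numeric(1)))
  expect_equal(tl$total, lh + tl$contrastive)
  expect_equal(tl$hungarian, lh)
  # doubling lambda4 doubles the total
  w2 <- loss_weights(lambda4 = 2)
  expect_equal(total_loss(batch, w2)$total, 2 * tl$total, tolerance = 1e-12)
  # switching CL off leaves the pure set-prediction objective
  expect_equal(total_loss(batch, w, contrastive = FALSE)$total, lh)
  # background-only batch: contrastive term is 0, total finite
  empty <- list(list(gt = pad_ground_truth(integer(0), matrix(numeric(0), 0, 4), 3L),
                     pred_probs = random_probs(3, 4), pred_boxes = random_box(3),
                     reps = matrix(rnorm(9), 3), h = 1:3))
  expect_equal(total_loss(empty, w)$contrastive, 0)
  expect_true(is.finite(total_loss(empty, w)$total))
})

test_that("graph and numeric losses agree on a real forward pass", {
  cfg <- tiny_detector_config(num_classes = 3)
  params <- detector_init(cfg, seed = 9)
  scenes <- lapply(1:2, function(i) {
    sc <- tiny_scene(seed = i + 40, num_classes = 3)
    sc$objects <- list(list(class_id = (i - 1L) %% 3L, box = c(0.4, 0.5, 0.3, 0.2)),
                       list(class_id = 2L, box = c(0.7, 0.3, 0.2, 0.3)))
    sc
  })
  w <- loss_weights()
  P <- lapply(params, ad_const)
  bl <- tooldetr:::batch_loss_graph(P, cfg, scenes, w)
  # numeric reference path
  batch <- lapply(scenes, function(sc) {
    fw <- detector_forward(params, cfg, sc$image)
    gt <- pad_ground_truth(tooldetr:::scene_classes(sc),
                           tooldetr:::scene_boxes(sc), cfg$num_queries)
    h <- match_predictions(gt, fw$class_probs, fw$boxes, w)$h
    list(gt = gt, pred_probs = fw$class_probs, pred_boxes = fw$boxes,
         reps = fw$reps, h = h)
  })
  ref <- total_loss(batch, w)
  expect_equal(bl$total, ref$total, tolerance = 1e-8)
  expect_equal(bl$hungarian, ref$hungarian, tolerance = 1e-8)
  expect_equal(bl$contrastive, ref$contrastive, tolerance = 1e-8)
})

test_that("one contrastive gradient step increases class separation", {
  set.seed(13)
  d <- 6; Q <- 6
  lbls <- c(0L, 0L, 1L, 1L, 2L, 2L)
  reps0 <- matrix(rnorm(Q * d), Q, d)
  gt <- pad_ground_truth(lbls, random_box(Q), Q)
  sep <- function(R) {
    xn <- R / sqrt(rowSums(R * R))
    S <- tcrossprod(xn)
    same <- outer(lbls, lbls, "==") & !diag(Q)
    mean(S[same]) - mean(S[!outer(lbls, lbls, "==")])
  }
  tape <- ad_tape_begin()
  rn <- ad_leaf(reps0)
  items <- list(list(reps = rn, h = seq_len(Q), gt = gt))
  node <- tooldetr:::contrastive_loss_graph(items, loss_weights())
  ad_backward(tape, node)
  ad_tape_end()
  stepped <- reps0 - 0.1 * ad_grad(rn)
  expect_gt(sep(stepped), sep(reps0))
})
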