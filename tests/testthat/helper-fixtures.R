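# Shared fixtures: random boxes, tiny matched batches, and a permutation
# enumerator used by the brute-force assignment oracles.

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    shifted <- p + (p >= i)
    out <- rbind(out, cbind(i, shifted))
  }
  unname(out)
}

random_box <- function(n = 1) {
  cx <- runif(n, 0.2, 0.8); cy <- runif(n, 0.2, 0.8)
  w <- runif(n, 0.05, 0.4); h <- runif(n, 0.05, 0.4)
  cbind(cx, cy, w, h)
}

random_probs <- function(n, C1) {
  p <- matrix(rexp(n * C1), n, C1)
  p / rowSums(p)
}

# A random "matched" batch in the shape total_loss()/contrastive_loss()
# expect: bs samples with Q slots, random numbers of real objects, random
# representations, and the genuine optimal assignment.
random_batch <- function(bs, Q, C, d = 8, w = loss_weights()) {
  lapply(seq_len(bs), function(k) {
    n <- sample(0:min(3, Q), 1)
    gt <- pad_ground_truth(if (n > 0) sample(0:(C - 1), n, replace = TRUE) else integer(0),
                           if (n > 0) random_box(n) else matrix(numeric(0), 0, 4),
                           Q)
    probs <- random_probs(Q, C + 1L)
    boxes <- random_box(Q)
    h <- match_predictions(gt, probs, boxes, w)$h
    list(gt = gt, pred_probs = probs, pred_boxes = boxes,
         reps = matrix(rnorm(Q * d), Q, d), h = h)
  })
}

tiny_scene <- function(seed = 1, num_classes = 5, image_size = 64) {
  generate_scene(generator_config(num_classes = num_classes,
                                  image_size = image_size, seed = seed))
}
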