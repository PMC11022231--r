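make_tiny_fixture <- function(num_classes = 3, seed = 2) {
  cfg <- tiny_detector_config(num_classes = num_classes)
  list(cfg = cfg, params = detector_init(cfg, seed = seed),
       img = tiny_scene(seed = seed, num_classes = num_classes)$image)
}

test_that("end-to-end shape contract: one image yields exactly Q predictions", {
  fx <- make_tiny_fixture()
  out <- detector_forward(fx$params, fx$cfg, fx$img)
  expect_equal(dim(out$class_probs), c(16L, 4L))
  expect_equal(dim(out$boxes), c(16L, 4L))
  expect_equal(dim(out$reps), c(16L, 64L))
  expect_equal(rowSums(out$class_probs), rep(1, 16), tolerance = 1e-6)
  expect_true(all(out$boxes > 0 & out$boxes < 1))
})

test_that("two forward passes with frozen parameters are identical", {
  fx <- make_tiny_fixture()
  a <- detector_forward(fx$params, fx$cfg, fx$img)
  b <- detector_forward(fx$params, fx$cfg, fx$img)
  expect_identical(a$class_probs, b$class_probs)
  expect_identical(a$boxes, b$boxes)
})

test_that("encoder preserves sequence length and attention rows are normalized", {
  fx <- make_tiny_fixture()
  out <- detector_forward(fx$params, fx$cfg, fx$img, attention = TRUE)
  expect_equal(nrow(out$reps), fx$cfg$num_queries)
  aw <- out$attn[["enc.1"]]
  expect_length(aw, fx$cfg$num_heads)
  for (A in aw) {
    expect_equal(dim(A), c(320L, 320L))
    expect_equal(rowSums(A), rep(1, 320), tolerance = 1e-6)
  }
  # cross-attention over queries
  ca <- out$attn[["dec.1"]]
  expect_equal(dim(ca[[1]]), c(16L, 320L))
  expect_equal(rowSums(ca[[1]]), rep(1, 16), tolerance = 1e-6)
})

test_that("encode_tokens output length matches input for arbitrary L", {
  fx <- make_tiny_fixture()
  d <- fx$cfg$embed_dim
  for (L in c(1, 5, 33)) {
    toks <- matrix(rnorm(L * d), L, d)
    pos <- matrix(0, L, d)
    mem <- encode_tokens(toks, pos, fx$params, fx$cfg)
    expect_equal(dim(mem), c(L, d))
  }
  expect_error(detector_config(embed_dim = 60, num_heads = 8), "divisible")
})

test_that("decoder is equivariant to permuting memory with its positions", {
  fx <- make_tiny_fixture()
  d <- fx$cfg$embed_dim
  L <- 40
  set.seed(9)
  mem <- matrix(rnorm(L * d), L, d)
  pos <- matrix(rnorm(L * d, sd = 0.3), L, d)
  base <- decode_queries(mem, pos, fx$params, fx$cfg)
  perm <- sample(L)
  permuted <- decode_queries(mem[perm, ], pos[perm, ], fx$params, fx$cfg)
  expect_equal(base, permuted, tolerance = 1e-10)
})

test_that("strict zero queries provably collapse to identical outputs", {
  cfg <- tiny_detector_config(num_classes = 3, learned_query_embed = FALSE)
  params <- detector_init(cfg, seed = 4)
  img <- tiny_scene(seed = 4, num_classes = 3)$image
  out <- detector_forward(params, cfg, img)
  for (q in 2:cfg$num_queries)
    expect_equal(out$reps[q, ], out$reps[1, ], tolerance = 1e-10)
})

test_that("classification head is a single softmax layer with expected limits", {
  fx <- make_tiny_fixture(num_classes = 5)
  reps <- matrix(rnorm(8 * 64), 8, 64)
  p <- classify_head(reps, fx$params, fx$cfg)
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  # zero weights: uniform over C+1
  pz <- fx$params
  pz[["head.cls.W"]][] <- 0; pz[["head.cls.b"]][] <- 0
  expect_equal(classify_head(reps, pz, fx$cfg),
               matrix(1 / 6, 8, 6), tolerance = 1e-12)
  # softmax shift invariance
  pshift <- fx$params
  pshift[["head.cls.b"]][] <- pshift[["head.cls.b"]] + 3
  expect_equal(max.col(classify_head(reps, fx$params, fx$cfg)),
               max.col(classify_head(reps, pshift, fx$cfg)))
})

test_that("box head has exactly three affine layers and squashes to (0,1)", {
  fx <- make_tiny_fixture()
  nm <- grep("^head\\.box", names(fx$params), value = TRUE)
  expect_setequal(nm, c("head.box1.W", "head.box1.b", "head.box2.W",
                        "head.box2.b", "head.box3.W", "head.box3.b"))
  reps <- matrix(rnorm(50 * 64, sd = 5), 50, 64)
  b <- box_head(reps, fx$params, fx$cfg)
  expect_true(all(b > 0 & b < 1))
  pz <- fx$params
  pz[["head.box3.W"]][] <- 0; pz[["head.box3.b"]][] <- 0
  expect_equal(box_head(reps, pz, fx$cfg), matrix(0.5, 50, 4),
               tolerance = 1e-12)
})

test_that("postprocess filters by argmax class and threshold", {
  probs <- rbind(c(0.05, 0.9, 0.05),   # class 1 at 0.9
                 c(0.2, 0.2, 0.6),     # no-object argmax
                 c(0.45, 0.1, 0.45))   # tie -> first (class 0), below 0.5
  boxes <- matrix(0.5, 3, 4)
  out <- postprocess(probs, boxes, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$class_id, 1L)
  expect_equal(out$score, 0.9)
  expect_equal(nrow(postprocess(probs, boxes, 0)), 2)
  allno <- matrix(rep(c(0.1, 0.1, 0.8), 4), 4, 3, byrow = TRUE)
  expect_equal(nrow(postprocess(allno, matrix(0.5, 4, 4), 0.5)), 0)
})

test_that("every parameter group receives gradient on a generic batch", {
  cfg <- tiny_detector_config(num_classes = 3)
  params <- detector_init(cfg, seed = 6)
  sc <- tiny_scene(seed = 10, num_classes = 3)
  sc$objects <- list(list(class_id = 0L, box = c(0.4, 0.4, 0.3, 0.3)),
                     list(class_id = 2L, box = c(0.7, 0.6, 0.2, 0.25)))
  tape <- ad_tape_begin()
  Pn <- wrap_params(params)
  bl <- batch_loss_graph(Pn, cfg, list(sc), loss_weights())
  ad_backward(tape, bl$node)
  ad_tape_end()
  g <- collect_grads(Pn)
  groups <- list(backbone = "^bb\\.", projection = "^proj\\.",
                 encoder = "^enc\\.", decoder = "^dec\\.",
                 queries = "^qembed", class_head = "^head\\.cls",
                 box_head = "^head\\.box")
  for (nm in names(groups)) {
    tot <- sum(vapply(g[grep(groups[[nm]], names(g))],
                      function(x) sum(abs(x)), numeric(1)))
    expect_gt(tot, 0)
  }
})
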