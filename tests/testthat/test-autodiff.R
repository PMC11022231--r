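# Finite-difference validation of the autodiff engine. Each op is exercised
# inside a small composite graph so chain-rule interactions are covered.

fd_check <- function(build, x0, tol = 1e-6) {
  tape <- ad_tape_begin()
  leaf <- ad_leaf(x0)
  loss <- build(leaf)
  ad_backward(tape, loss)
  ad_tape_end()
  g <- ad_grad(leaf)
  eps <- 1e-6
  for (i in sample(length(x0), min(5, length(x0)))) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    fp <- as.numeric(ad_value(build(ad_const(xp))))
    fm <- as.numeric(ad_value(build(ad_const(xm))))
    expect_equal(g[i], (fp - fm) / (2 * eps), tolerance = tol)
  }
}

test_that("elementwise and matrix ops backpropagate exact gradients", {
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  B1 <- matrix(rnorm(6), 3, 2)
  B2 <- matrix(rnorm(8), 2, 4)
  fd_check(function(x) ad_sum(ad_matmul(x, ad_const(W))), A)
  fd_check(function(x) ad_sum(ad_matmul(x, ad_const(B1), ta = TRUE)), A)
  fd_check(function(x) ad_sum(ad_matmul(x, ad_const(B2), tb = TRUE)), A)
  fd_check(function(x) ad_sum(ad_mul(ad_relu(x), ad_sigmoid(x))), A)
  fd_check(function(x) ad_sum(ad_exp(ad_scale(x, 0.3))), A)
  fd_check(function(x) ad_sum(ad_log(ad_add_const(ad_abs(x), 1))), A)
  fd_check(function(x) ad_sum(ad_sqrt(ad_add_const(ad_mul(x, x), 0.1))), A)
  fd_check(function(x) ad_sum(ad_recip(ad_add_const(ad_mul(x, x), 1))), A)
})

test_that("softmax, layernorm and reductions backpropagate exact gradients", {
  set.seed(2)
  A <- matrix(rnorm(12), 3, 4)
  g <- matrix(runif(4, 0.5, 1.5), 1)
  b <- matrix(rnorm(4), 1)
  fd_check(function(x) ad_sum(ad_mul(ad_softmax_rows(x), ad_const(A + 2))), A)
  fd_check(function(x) ad_sum(ad_mul(ad_layernorm(x, ad_const(g), ad_const(b)),
                                     ad_const(A))), A, tol = 1e-5)
  fd_check(function(x) ad_sum(ad_mul(ad_rowsums(x), ad_const(matrix(1:3, 3)))), A)
  fd_check(function(x) ad_sum(ad_scale_rows(x, ad_const(matrix(c(1, -2, 0.5), 3)))), A)
})

test_that("gather, slicing and stacking ops backpropagate exact gradients", {
  set.seed(3)
  A <- matrix(rnorm(20), 5, 4)
  fd_check(function(x) ad_sum(ad_mul(ad_rows(x, c(2, 2, 5)), ad_const(matrix(1, 3, 4) * 2))), A)
  fd_check(function(x) ad_sum(ad_mul(ad_cols(x, c(1, 3)), ad_const(matrix(3, 5, 2)))), A)
  fd_check(function(x) ad_sum(ad_gather(x, cbind(c(1, 4, 4), c(2, 3, 3)))), A)
  M1 <- matrix(rnorm(40), 10, 4)
  M2 <- matrix(rnorm(40), 5, 8)
  fd_check(function(x) ad_sum(ad_mul(ad_rbind(list(x, x)), ad_const(M1))), A)
  fd_check(function(x) ad_sum(ad_mul(ad_cbind(list(x, x)), ad_const(M2))), A)
  fd_check(function(x) ad_sum(ad_pmax2(x, ad_const(A * 0))), A)
  fd_check(function(x) ad_sum(ad_pmin2(ad_mul(x, x), ad_const(A * 0 + 0.5))), A)
})

test_that("im2col convolution matches direct convolution and its gradient", {
  set.seed(4)
  h <- 5L; w <- 6L; cin <- 2L; cout <- 3L; k <- 3L
  X <- matrix(rnorm(h * w * cin), h * w, cin)
  Wt <- matrix(rnorm(k * k * cin * cout), k * k * cin, cout)
  # direct reference convolution (zero padding, stride 1)
  ref <- matrix(0, h * w, cout)
  for (y in 1:h) for (x in 1:w) {
    acc <- numeric(cout)
    for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
      yy <- y + dy - 1L; xx <- x + dx - 1L
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) {
        o <- dy * k + dx + 1L
        for (cc in 1:cin)
          acc <- acc + X[(yy - 1) * w + xx, cc] * Wt[(cc - 1) * k * k + o, ]
      }
    }
    ref[(y - 1) * w + x, ] <- acc
  }
  cols <- ad_im2col(ad_const(X), h, w, k, 1L)
  out <- ad_matmul(cols, ad_const(Wt))
  expect_equal(ad_value(out), ref, tolerance = 1e-12)
  fd_check(function(xn) ad_sum(ad_mul(
    ad_matmul(ad_im2col(xn, h, w, k, 1L), ad_const(Wt)),
    ad_const(ref + 1))), X, tol = 1e-5)
})

test_that("strided im2col halves spatial size with ceiling arithmetic", {
  X <- matrix(rnorm(49), 49, 1)
  cols <- ad_im2col(ad_const(X), 7L, 7L, 3L, 2L)
  expect_equal(attr(cols, "h_out"), 4L)
  expect_equal(attr(cols, "w_out"), 4L)
})

test_that("whole-model gradients agree with finite differences", {
  set.seed(11)
  cfg <- tiny_detector_config(num_classes = 3)
  params <- detector_init(cfg, seed = 3)
  sc <- tiny_scene(seed = 5, num_classes = 3)
  sc$objects <- list(list(class_id = 1L, box = c(0.4, 0.5, 0.3, 0.2)))
  w <- loss_weights()
  tape <- ad_tape_begin()
  Pn <- wrap_params(params)
  bl <- batch_loss_graph(Pn, cfg, list(sc), w)
  ad_backward(tape, bl$node)
  ad_tape_end()
  grads <- collect_grads(Pn)
  eps <- 1e-5
  for (nm in c("bb.stem.W", "proj.2.W", "enc.1.sa.q.W", "dec.2.ca.v.W",
               "qembed", "head.cls.W", "head.box3.b")) {
    i <- sample(length(params[[nm]]), 1)
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
    p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
    f2 <- batch_loss_graph(wrap_params(p2), cfg, list(sc), w)$total
    f3 <- batch_loss_graph(wrap_params(p3), cfg, list(sc), w)$total
    fd <- (f2 - f3) / (2 * eps)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-3)
  }
})
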