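test_that("channel bookkeeping: groups tile the block width", {
  cfg <- backbone_config("full", scale_groups = 4, group_width = 26)
  ch <- tooldetr:::stage_channels(cfg, 1)
  expect_equal(unname(ch["inner"]), 104L)
  expect_equal(unname(ch["inner"]) %/% cfg$scale_groups, 26L)
  expect_error(res2net_block(matrix(0, 16, 30), 4, 4, scale_groups = 4,
                             group_width = 8), "not scale_groups")
  expect_error(backbone_config(scale_groups = 1), "scale_groups")
  expect_error(backbone_config(tap_layers = c(1, 2, 3)), "exactly two")
})

test_that("zeroed transforms reduce the block to its residual pathway", {
  set.seed(1)
  x <- matrix(rnorm(36 * 8), 36, 8)
  params <- tooldetr:::init_res2net_block(list(), "blk", 8L, 8L, 8L, 4L, 2L)
  for (nm in names(params)) params[[nm]][] <- 0
  P <- lapply(params, ad_const)
  out <- tooldetr:::res2net_block_fwd(P, "blk", ad_const(x), 6, 6, 4L, 2L, 8L)
  expect_equal(ad_value(out), pmax(x, 0))
})

test_that("later groups have strictly larger receptive fields", {
  # finite-footprint oracle: gradient of one center output cell w.r.t. the
  # input must touch a wider neighbourhood for each successive group
  set.seed(2)
  g <- 4L; wg <- 2L; C <- 8L; h <- w <- 9L
  params <- tooldetr:::init_res2net_block(list(), "blk", C, C, C, g, wg)
  # positive weights and inputs keep every ReLU active, so the gradient
  # footprint reflects pure connectivity rather than which units fired
  params <- lapply(params, abs)
  x0 <- matrix(abs(rnorm(h * w * C)) + 0.1, h * w, C)
  center <- ((h %/% 2) * w + w %/% 2) + 1L
  radius_for_group <- function(gi) {
    tape <- ad_tape_begin()
    xn <- ad_leaf(x0)
    P <- lapply(params, ad_const)
    z <- ad_relu(tooldetr:::nn_conv(P, "blk.in", xn, h, w, 1L)$x)
    ys <- vector("list", g)
    ys[[1]] <- ad_cols(z, 1:wg)
    prev <- NULL
    for (i in 2:g) {
      xi <- ad_cols(z, ((i - 1L) * wg + 1L):(i * wg))
      inp <- if (i == 2L) xi else ad_add(xi, prev)
      prev <- ad_relu(tooldetr:::nn_conv(P, paste0("blk.g", i), inp, h, w, 3L)$x)
      ys[[i]] <- prev
    }
    root <- ad_sum(ad_rows(ys[[gi]], center))
    ad_backward(tape, root)
    ad_tape_end()
    gr <- ad_grad(xn)
    if (is.null(gr)) return(0)
    touched <- which(rowSums(abs(gr)) > 1e-12)
    ry <- (touched - 1L) %/% w
    rx <- (touched - 1L) %% w
    max(abs(ry - h %/% 2), abs(rx - w %/% 2))
  }
  radii <- vapply(2:g, radius_for_group, numeric(1))
  expect_equal(radii, c(1, 2, 3))
})

test_that("tap shapes follow stride arithmetic for both variants", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  taps <- extract_features(img, backbone_config("tiny"), seed = 3)
  expect_length(taps, 2)
  expect_equal(c(taps[[1]]$h, taps[[1]]$w, taps[[1]]$stride), c(16, 16, 4))
  expect_equal(c(taps[[2]]$h, taps[[2]]$w, taps[[2]]$stride), c(8, 8, 8))
  # determinism with frozen parameters
  set.seed(1); p <- tooldetr:::init_backbone(list(), backbone_config("tiny"))
  t1 <- extract_features(img, backbone_config("tiny"), params = p)
  t2 <- extract_features(img, backbone_config("tiny"), params = p)
  expect_identical(t1[[1]]$values, t2[[1]]$values)
})

test_that("full variant taps layers 2 and 4 at strides 8 and 32", {
  img <- array(runif(320 * 320 * 3), c(320, 320, 3))
  taps <- extract_features(img, backbone_config("full"), seed = 1)
  expect_equal(c(taps[[1]]$h, taps[[1]]$w, taps[[1]]$stride), c(40, 40, 8))
  expect_equal(c(taps[[2]]$h, taps[[2]]$w, taps[[2]]$stride), c(10, 10, 32))
  expect_equal(ncol(taps[[1]]$values) %% 4, 0)
})

test_that("projection reaches the common width and scales stay isolated", {
  fm <- list(values = matrix(rnorm(100 * 12), 100, 12), h = 10, w = 10,
             scale_id = 1)
  pm <- project(fm, embed_dim = 7)
  expect_equal(ncol(pm$values), 7)
  # identity weights reproduce the input
  idw <- list(W = diag(12), b = matrix(0, 1, 12))
  expect_equal(project(fm, 12, weights = idw)$values, fm$values)
  # per-scale parameters: perturbing scale 1's projection leaves scale 2 alone
  cfg <- tiny_detector_config(num_classes = 3)
  params <- detector_init(cfg, seed = 5)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  base <- detector_forward(params, cfg, img)
  p2 <- params
  p2[["proj.1.W"]] <- p2[["proj.1.W"]] + 0.5
  taps1 <- extract_features(img, cfg$backbone,
                            params = params[grep("^bb\\.", names(params))])
  prj <- function(pp, s, tap) tap$values %*% pp[[sprintf("proj.%d.W", s)]]
  expect_equal(prj(params, 2, taps1[[2]]), prj(p2, 2, taps1[[2]]))
  expect_false(isTRUE(all.equal(prj(params, 1, taps1[[1]]),
                                prj(p2, 1, taps1[[1]]))))
  expect_error(project(fm, 0), "embed_dim")
})
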