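# Geometric data augmentation. Six transforms, each applied independently
# with probability p (default 1/3): horizontal flip, vertical flip, rotation
# (+-15 deg), isotropic scale jitter (0.8-1.2), translation (+-10%), and
# shear (+-10 deg). Pixels are warped by inverse mapping with
# nearest-neighbour sampling (clamped to the image); boxes are transformed
# through the same affine map (axis-aligned hull of the four corners),
# re-clipped, and dropped when almost nothing of the object survives.

affine_identity <- function() diag(3)

affine_about_center <- function(m2x2) {
  A <- diag(3)
  A[1:2, 1:2] <- m2x2
  shift <- c(0.5, 0.5) - m2x2 %*% c(0.5, 0.5)
  A[1:2, 3] <- shift
  A
}

#' Augment a scene with random geometric transforms
#'
#' @param scene a scene (see [generate_scene()]).
#' @param p per-transform application probability.
#' @param seed RNG seed.
#' @param min_area_px minimum surviving object area in squared pixels.
#' @return the transformed scene; objects clipped away are removed.
#' @export
augment <- function(scene, p = 1 / 3, seed = NULL, min_area_px = 4) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  apply_flags <- stats::runif(6) < p
  hflip <- apply_flags[1]
  vflip <- apply_flags[2]
  rot <- if (apply_flags[3]) stats::runif(1, -15, 15) * pi / 180 else 0
  scl <- if (apply_flags[4]) stats::runif(1, 0.8, 1.2) else 1
  tr <- if (apply_flags[5]) stats::runif(2, -0.1, 0.1) else c(0, 0)
  shr <- if (apply_flags[6]) tan(stats::runif(1, -10, 10) * pi / 180) else 0
  transform_scene(scene, hflip = hflip, vflip = vflip, rotation = rot,
                  scale = scl, translate = tr, shear = shr,
                  min_area_px = min_area_px)
}

#' Apply a fixed affine transform to a scene
#'
#' Deterministic core of [augment()]; exposed so individual transforms can
#' be applied and composed exactly.
#'
#' @param scene a scene.
#' @param hflip,vflip mirror about the vertical/horizontal center line.
#' @param rotation radians about the image center.
#' @param scale isotropic factor about the center.
#' @param translate length-2 normalized offset.
#' @param shear horizontal shear coefficient.
#' @param min_area_px minimum surviving object area in squared pixels.
#' @export
transform_scene <- function(scene, hflip = FALSE, vflip = FALSE, rotation = 0,
                            scale = 1, translate = c(0, 0), shear = 0,
                            min_area_px = 4) {
  H <- dim(scene$image)[1]; W <- dim(scene$image)[2]
  A <- affine_identity()
  if (hflip) A <- affine_about_center(matrix(c(-1, 0, 0, 1), 2)) %*% A
  if (vflip) A <- affine_about_center(matrix(c(1, 0, 0, -1), 2)) %*% A
  if (rotation != 0)
    A <- affine_about_center(matrix(c(cos(rotation), sin(rotation),
                                      -sin(rotation), cos(rotation)), 2)) %*% A
  if (scale != 1) A <- affine_about_center(diag(2) * scale) %*% A
  if (shear != 0) A <- affine_about_center(matrix(c(1, 0, shear, 1), 2)) %*% A
  if (any(translate != 0)) {
    Tm <- affine_identity(); Tm[1:2, 3] <- translate
    A <- Tm %*% A
  }
  if (all(abs(A - diag(3)) < 1e-15)) return(scene)

  Ainv <- solve(A)
  # output pixel centers in normalized coords, row-major
  u <- (rep(seq_len(W), times = H) - 0.5) / W
  v <- (rep(seq_len(H), each = W) - 0.5) / H
  src <- Ainv %*% rbind(u, v, 1)
  cols <- pmin(pmax(ceiling(src[1, ] * W), 1L), W)
  rows <- pmin(pmax(ceiling(src[2, ] * H), 1L), H)
  idx <- cbind(as.vector(rows), as.vector(cols))
  image <- array(0L, dim(scene$image))
  for (ch in 1:3) {
    plane <- scene$image[, , ch]
    image[, , ch] <- matrix(plane[idx], H, W, byrow = TRUE)
  }

  objects <- list()
  for (ob in scene$objects) {
    xy <- box_cxcywh_to_xyxy(ob$box)
    corners <- rbind(c(xy[1], xy[2]), c(xy[3], xy[2]),
                     c(xy[1], xy[4]), c(xy[3], xy[4]))
    tc <- t(A %*% rbind(t(corners), 1))[, 1:2, drop = FALSE]
    nb <- clip_box(drop(box_xyxy_to_cxcywh(c(min(tc[, 1]), min(tc[, 2]),
                                             max(tc[, 1]), max(tc[, 2])))),
                   min_area = min_area_px / (H * W))
    if (!is.null(nb))
      objects[[length(objects) + 1L]] <- list(class_id = ob$class_id, box = nb)
  }
  structure(list(image = image, objects = objects), class = "scene")
}
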