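#' Synthetic laparoscopic scene generator configuration
#'
#' Generates endoscope-like frames containing elongated instrument shapes
#' on a tissue-colored background. Each class renders a distinct tip
#' geometry (jaws, prongs, hook, blades, wedge, tube, ring) and albedo, so
#' classes are separable in principle while sharing the thin-shaft
#' structure that makes surgical tools hard to localize. The generator
#' reproduces the statistical traits the detector must handle: frames with
#' 0--3 instruments, long-tailed class frequencies, large scale variation,
#' optional partial occlusion, and specular highlight noise.
#'
#' @param image_size square image side in pixels.
#' @param num_classes number of foreground classes (at most 7 distinct
#'   geometries are defined; more classes reuse geometries with distinct
#'   albedos).
#' @param class_frequencies sampling probabilities, long-tailed by default;
#'   must sum to 1.
#' @param objects_per_scene inclusive integer range of instruments per frame.
#' @param scale_range instrument length as a fraction of the image side.
#' @param occlusion_prob probability that an added instrument is deliberately
#'   placed to overlap an existing one.
#' @param specular_noise_level expected fraction of pixels hit by specular
#'   highlight speckles.
#' @param seed default RNG seed for generation.
#' @return a `generator_config` list.
#' @export
generator_config <- function(image_size = 64L, num_classes = 7L,
                             class_frequencies = NULL,
                             objects_per_scene = c(0L, 3L),
                             scale_range = c(0.25, 0.7),
                             occlusion_prob = 0.3,
                             specular_noise_level = 0.01,
                             seed = 1L) {
  if (is.null(class_frequencies)) {
    base <- c(0.35, 0.22, 0.15, 0.10, 0.08, 0.06, 0.04)
    class_frequencies <- if (num_classes <= 7L) {
      f <- base[seq_len(num_classes)]; f / sum(f)
    } else {
      f <- c(base, rep(0.02, num_classes - 7L)); f / sum(f)
    }
  }
  if (length(class_frequencies) != num_classes)
    stop("config field class_frequencies: needs one entry per class")
  if (abs(sum(class_frequencies) - 1) > 1e-9)
    stop("config field class_frequencies: must sum to 1")
  if (length(objects_per_scene) != 2L || objects_per_scene[1] > objects_per_scene[2])
    stop("config field objects_per_scene: must be an increasing range")
  if (scale_range[1] >= scale_range[2] || scale_range[1] <= 0)
    stop("config field scale_range: min must be positive and below max")
  if (occlusion_prob < 0 || occlusion_prob > 1)
    stop("config field occlusion_prob: must be in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 num_classes = as.integer(num_classes),
                 class_frequencies = class_frequencies,
                 objects_per_scene = as.integer(objects_per_scene),
                 scale_range = scale_range,
                 occlusion_prob = occlusion_prob,
                 specular_noise_level = specular_noise_level,
                 seed = as.integer(seed)),
            class = "generator_config")
}

tool_albedo <- function(class_id) {
  palette <- rbind(c(215, 215, 222),   # grasper: bright steel
                   c(120, 132, 176),   # bipolar: blue-gray
                   c(204, 172, 92),    # hook: brass
                   c(168, 204, 172),   # scissors: green-steel
                   c(164, 120, 166),   # clipper: purple-gray
                   c(88, 162, 172),    # irrigator: teal tube
                   c(232, 222, 198))   # specimen bag: off-white
  palette[(class_id %% 7L) + 1L, ]
}

# distance from pixel centers to segment p0-p1 (all in pixel units)
seg_dist <- function(px, py, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(pmax(((px - p0[1]) * vx + (py - p0[2]) * vy) / len2, 0), 1)
  sqrt((px - (p0[1] + t * vx))^2 + (py - (p0[2] + t * vy))^2)
}

# Render one instrument mask on the pixel grid. Returns logical vector
# (row-major over the H x W grid like the image matrices).
render_tool <- function(class_id, center, angle, len, px, py) {
  u <- c(cos(angle), sin(angle))
  n <- c(-u[2], u[1])
  r <- max(len * 0.055, 1.2)
  tip <- center + u * len / 2
  tail <- center - u * len / 2
  shaft_end <- center + u * len * 0.22
  mask <- seg_dist(px, py, tail, shaft_end) <= r
  geom <- class_id %% 7L
  if (geom == 0L) {                 # grasper: two diverging jaws
    for (sgn in c(-1, 1)) {
      jaw <- rot2(u, sgn * 0.45)
      mask <- mask | seg_dist(px, py, shaft_end, shaft_end + jaw * len * 0.32) <= r * 0.8
    }
  } else if (geom == 1L) {          # bipolar: two parallel prongs
    for (sgn in c(-1, 1)) {
      off <- n * r * 2.2 * sgn
      mask <- mask | seg_dist(px, py, shaft_end + off, tip + off) <= r * 0.7
    }
  } else if (geom == 2L) {          # hook: shaft plus J-shaped arc
    cen <- shaft_end + n * len * 0.12
    rad <- len * 0.16
    d <- sqrt((px - cen[1])^2 + (py - cen[2])^2)
    ang <- atan2(py - cen[2], px - cen[1]) - angle
    arc <- abs(d - rad) <= r * 0.8 & cos(ang) > -0.35
    mask <- mask | arc
  } else if (geom == 3L) {          # scissors: two crossing open blades
    for (sgn in c(-1, 1)) {
      blade <- rot2(u, sgn * 0.6)
      base <- shaft_end - blade * len * 0.08
      mask <- mask | seg_dist(px, py, base, base + blade * len * 0.38) <= r * 0.65
    }
  } else if (geom == 4L) {          # clipper: filled wedge tip
    a <- shaft_end
    b <- shaft_end + rot2(u, 0.5) * len * 0.3
    cc <- shaft_end + rot2(u, -0.5) * len * 0.3
    mask <- mask | in_triangle(px, py, a, b, cc)
  } else if (geom == 5L) {          # irrigator: straight tube, blunt disc tip
    mask <- seg_dist(px, py, tail, tip) <= r * 0.9
    mask <- mask | (sqrt((px - tip[1])^2 + (py - tip[2])^2) <= r * 1.8)
  } else {                          # specimen bag: ring on a short shaft
    cen <- shaft_end + u * len * 0.18
    rad <- len * 0.2
    d <- sqrt((px - cen[1])^2 + (py - cen[2])^2)
    mask <- mask | (abs(d - rad) <= r)
  }
  mask
}

rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])

in_triangle <- function(px, py, a, b, cc) {
  s1 <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  s2 <- (cc[1] - b[1]) * (py - b[2]) - (cc[2] - b[2]) * (px - b[1])
  s3 <- (a[1] - cc[1]) * (py - cc[2]) - (a[2] - cc[2]) * (px - cc[1])
  (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
}

#' Generate one synthetic scene
#'
#' Deterministic given `(config, seed)`. Annotations are the exact pixel
#' bounding boxes of each instrument's own rendered mask (before any
#' overdraw by later instruments, which is what produces partial
#' occlusion).
#'
#' @param config a [generator_config()].
#' @param seed RNG seed; defaults to the config seed.
#' @param keep_masks attach each object's rendered pixel mask (logical
#'   vector, row-major) to the annotation -- used for fidelity checks.
#' @return a `scene`: list with `image` (`H x W x 3` array, 0--255) and
#'   `objects` (list of `class_id` (0-based) + `box` (normalized cxcywh)).
#' @export
generate_scene <- function(config = generator_config(), seed = config$seed,
                           keep_masks = FALSE) {
  set.seed(seed)
  S <- config$image_size
  # pixel-center coordinates, row-major (row y, then col x) to match
  # image_to_matrix()
  px <- rep(seq_len(S) - 0.5, times = S)
  py <- rep(seq_len(S) - 0.5, each = S)
  # tissue background: reddish base + smooth illumination + grain
  base <- c(148, 62, 58) + stats::rnorm(3, 0, 8)
  gx <- stats::runif(1); gy <- stats::runif(1)
  illum <- 1 - 0.55 * sqrt((px / S - gx)^2 + (py / S - gy)^2)
  img <- vapply(1:3, function(ch)
    pmin(pmax(base[ch] * illum + stats::rnorm(S * S, 0, 6), 0), 255),
    numeric(S * S))

  n_obj <- sample(config$objects_per_scene[1]:config$objects_per_scene[2], 1)
  objects <- list()
  prev_tips <- list()
  if (n_obj > 0) for (k in seq_len(n_obj)) {
    class_id <- sample(config$num_classes, 1, prob = config$class_frequencies) - 1L
    len <- stats::runif(1, config$scale_range[1], config$scale_range[2]) * S
    occlude <- length(prev_tips) > 0 && stats::runif(1) < config$occlusion_prob
    center <- if (occlude) {
      anchor <- prev_tips[[sample(length(prev_tips), 1)]]
      pmin(pmax(anchor + stats::rnorm(2, 0, len * 0.2), 0.15 * S), 0.85 * S)
    } else {
      c(stats::runif(1, 0.2, 0.8), stats::runif(1, 0.2, 0.8)) * S
    }
    angle <- stats::runif(1, 0, 2 * pi)
    mask <- render_tool(class_id, center, angle, len, px, py)
    if (sum(mask) < 4) next
    shade <- 0.75 + 0.5 * pmax(0, sin(angle) * (px - center[1]) / S +
                                    cos(angle) * (py - center[2]) / S + 0.5)
    col <- tool_albedo(class_id)
    for (ch in 1:3) img[mask, ch] <- pmin(col[ch] * shade[mask] +
                                            stats::rnorm(sum(mask), 0, 5), 255)
    xs <- px[mask]; ys <- py[mask]
    # tight pixel box: pixels occupy [c-0.5, c+0.5]
    x1 <- (min(xs) - 0.5) / S; x2 <- (max(xs) + 0.5) / S
    y1 <- (min(ys) - 0.5) / S; y2 <- (max(ys) + 0.5) / S
    ob <- list(class_id = class_id,
               box = drop(box_xyxy_to_cxcywh(c(x1, y1, x2, y2))))
    if (keep_masks) ob$mask <- mask
    objects[[length(objects) + 1L]] <- ob
    prev_tips[[length(prev_tips) + 1L]] <- center
  }
  # specular highlights: small saturated speckles
  n_spec <- stats::rpois(1, config$specular_noise_level * S * S / 3)
  if (n_spec > 0) for (s in seq_len(n_spec)) {
    c0 <- stats::runif(2, 0, S)
    hit <- (px - c0[1])^2 + (py - c0[2])^2 <= stats::runif(1, 0.5, 2)^2
    img[hit, ] <- 255
  }
  image <- array(0L, c(S, S, 3))
  for (ch in 1:3) image[, , ch] <- matrix(as.integer(round(img[, ch])),
                                          S, S, byrow = TRUE)
  structure(list(image = image, objects = objects), class = "scene")
}

#' Generate a list of scenes
#'
#' Scene `i` is generated with seed `seed + i - 1`, so any prefix of a
#' dataset is reproducible independently of its length.
#' @param config a [generator_config()].
#' @param n number of scenes.
#' @param seed base seed (defaults to the config seed).
#' @export
generate_scenes <- function(config = generator_config(), n, seed = config$seed) {
  if (n < 1) stop("n_scenes must be >= 1")
  lapply(seq_len(n), function(i) generate_scene(config, seed + i - 1L))
}

#' Write a synthetic dataset to disk in COCO layout
#'
#' Renders `n_scenes` scenes, writes PNG images and a single COCO JSON
#' annotation file (`annotations.json`) into `out_dir`.
#'
#' @param config a [generator_config()].
#' @param n_scenes number of scenes (>= 1).
#' @param out_dir output directory (created if missing).
#' @param seed base seed.
#' @return (invisibly) the list of scenes.
#' @export
generate_dataset <- function(config, n_scenes, out_dir, seed = config$seed) {
  if (n_scenes < 1) stop("n_scenes must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  scenes <- generate_scenes(config, n_scenes, seed)
  for (i in seq_along(scenes)) {
    png::writePNG(scenes[[i]]$image / 255,
                  file.path(out_dir, sprintf("scene_%05d.png", i)))
  }
  write_coco(scenes, file.path(out_dir, "annotations.json"),
             file_names = sprintf("scene_%05d.png", seq_along(scenes)),
             num_classes = config$num_classes)
  invisible(scenes)
}
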