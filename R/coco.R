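#' Write scenes to a COCO detection JSON file
#'
#' Boxes are converted from the internal normalized cxcywh form to COCO
#' pixel `[x, y, width, height]` (top-left origin, 0-based, half-open).
#' Coordinates are written as floating point, so a write/read round trip is
#' lossless up to JSON number precision.
#'
#' @param scenes list of scenes (`image` may be NULL when only annotations
#'   are needed, but then `image_size` must be supplied).
#' @param path output JSON path.
#' @param file_names optional per-scene image file names.
#' @param num_classes category count for the categories table.
#' @param image_size fallback image side when a scene carries no image.
#' @export
write_coco <- function(scenes, path, file_names = NULL, num_classes = 7L,
                       image_size = NULL) {
  images <- vector("list", length(scenes))
  annotations <- list()
  aid <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    if (!is.null(sc$image)) { H <- dim(sc$image)[1]; W <- dim(sc$image)[2] }
    else if (!is.null(image_size)) { H <- image_size; W <- image_size }
    else stop("scene ", i, " has no image and no image_size was given")
    images[[i]] <- list(id = i, width = W, height = H,
                        file_name = if (is.null(file_names)) sprintf("scene_%05d.png", i)
                                    else file_names[i])
    for (ob in sc$objects) {
      aid <- aid + 1L
      xy <- box_cxcywh_to_xyxy(ob$box)
      bbox <- c(xy[1] * W, xy[2] * H, (xy[3] - xy[1]) * W, (xy[4] - xy[2]) * H)
      annotations[[aid]] <- list(id = aid, image_id = i,
                                 category_id = ob$class_id + 1L,
                                 bbox = bbox, area = bbox[3] * bbox[4],
                                 iscrowd = 0L)
    }
  }
  categories <- lapply(seq_len(num_classes), function(k)
    list(id = k, name = paste0("tool_", k - 1L)))
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = categories),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO detection JSON file into scenes
#'
#' @param path JSON path.
#' @param images_dir directory holding the image files; images are loaded
#'   when found, otherwise scenes carry `image = NULL` plus `width`/`height`.
#' @return list of scenes (normalized cxcywh boxes, 0-based class ids).
#' @export
read_coco <- function(path, images_dir = dirname(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(doc$categories)) stop("missing category table in ", path)
  if (is.null(doc$images)) stop("missing images array in ", path)
  cat_ids <- vapply(doc$categories, function(cc) as.integer(cc$id), integer(1))
  scenes <- list()
  dims <- list()
  for (im in doc$images) {
    id <- as.integer(im$id)
    img <- NULL
    f <- file.path(images_dir, im$file_name)
    if (!is.null(im$file_name) && file.exists(f)) {
      arr <- png::readPNG(f)
      img <- array(as.integer(round(arr * 255)), dim(arr))[, , 1:3, drop = FALSE]
    }
    scenes[[as.character(id)]] <- structure(
      list(image = img, objects = list(),
           width = as.integer(im$width), height = as.integer(im$height)),
      class = "scene")
    dims[[as.character(id)]] <- c(as.integer(im$width), as.integer(im$height))
  }
  for (an in doc$annotations) {
    key <- as.character(as.integer(an$image_id))
    if (is.null(scenes[[key]]))
      stop("annotation ", an$id, " references unknown image_id ", an$image_id)
    if (!(as.integer(an$category_id) %in% cat_ids))
      stop("annotation ", an$id, " references unknown category_id ",
           an$category_id)
    WH <- dims[[key]]
    bb <- as.numeric(unlist(an$bbox))
    if (length(bb) != 4 || bb[3] <= 0 || bb[4] <= 0 ||
        bb[1] < -1e-6 || bb[2] < -1e-6 ||
        bb[1] + bb[3] > WH[1] + 1e-6 || bb[2] + bb[4] > WH[2] + 1e-6)
      stop("annotation ", an$id, ": box out of image bounds")
    box <- drop(box_xyxy_to_cxcywh(c(bb[1] / WH[1], bb[2] / WH[2],
                                     (bb[1] + bb[3]) / WH[1],
                                     (bb[2] + bb[4]) / WH[2])))
    scenes[[key]]$objects[[length(scenes[[key]]$objects) + 1L]] <-
      list(class_id = as.integer(an$category_id) - 1L, box = box)
  }
  unname(scenes)
}

#' Write detections in COCO results format
#'
#' @param detections data.frame with `image_id`, `class_id` (0-based),
#'   `score`, and normalized `cx`, `cy`, `w`, `h`.
#' @param path output JSON path.
#' @param image_size image side in pixels used to scale boxes.
#' @export
write_coco_results <- function(detections, path, image_size) {
  out <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    xy <- box_cxcywh_to_xyxy(c(d$cx, d$cy, d$w, d$h))
    list(image_id = d$image_id, category_id = d$class_id + 1L,
         bbox = c(xy[1], xy[2], xy[3] - xy[1], xy[4] - xy[2]) * image_size,
         score = d$score)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
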