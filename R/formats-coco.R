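#' Read a COCO JSON annotation file
#'
#' COCO stores boxes as `[x, y, width, height]` with 0-based corner
#' coordinates; they map directly onto the internal half-open convention as
#' `Box(x, y, x + width, y + height)`. Category names are mapped to worm
#' classes through `class_table`.
#'
#' @param path Path to a COCO JSON file with `images`, `annotations` and
#'   `categories` blocks.
#' @param class_table Named character vector mapping category names to
#'   `"focal"`/`"gfp"`.
#' @return A list of [worm_annotation()], one per entry of `images` (in file
#'   order), keyed by `file_name`. An annotation referencing an unknown
#'   image id is an error naming the id.
#' @export
read_coco_json <- function(path, class_table = default_class_table()) {
  coco <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (block in c("images", "annotations", "categories")) {
    if (is.null(coco[[block]])) stop("COCO file ", path, " lacks '", block, "'")
  }
  cat_class <- vapply(coco$categories, function(ct) {
    map_class_names(ct$name, class_table)
  }, character(1))
  names(cat_class) <- vapply(coco$categories, function(ct) as.character(ct$id),
                             character(1))
  img_ids <- vapply(coco$images, function(im) as.character(im$id), character(1))
  objects <- lapply(seq_along(coco$images), function(i) empty_objects())
  names(objects) <- img_ids
  for (a in coco$annotations) {
    iid <- as.character(a$image_id)
    if (!iid %in% img_ids) {
      stop("COCO annotation references missing image id ", iid)
    }
    cid <- as.character(a$category_id)
    if (!cid %in% names(cat_class)) {
      stop("COCO annotation references missing category id ", cid)
    }
    bb <- as.numeric(unlist(a$bbox))
    objects[[iid]] <- rbind(objects[[iid]], data.frame(
      x_min = bb[1], y_min = bb[2],
      x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
      class = unname(cat_class[[cid]]), stringsAsFactors = FALSE
    ))
  }
  anns <- lapply(seq_along(coco$images), function(i) {
    im <- coco$images[[i]]
    worm_annotation(
      image_id = im$file_name, width = im$width, height = im$height,
      objects = objects[[as.character(im$id)]]
    )
  })
  names(anns) <- vapply(anns, function(a) a$image_id, character(1))
  anns
}

#' Write a COCO JSON annotation file
#'
#' The inverse of [read_coco_json()]: internal half-open boxes become
#' `[x_min, y_min, x_max - x_min, y_max - y_min]`. Categories are written as
#' ids 1 (`focal`) and 2 (`gfp`); a read/write round trip reproduces boxes
#' exactly.
#'
#' @param anns A list of [worm_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coco_json <- function(anns, path) {
  if (inherits(anns, "worm_annotation")) anns <- list(anns)
  stopifnot(all(vapply(anns, inherits, logical(1), "worm_annotation")))
  images <- lapply(seq_along(anns), function(i) {
    list(
      id = i, file_name = anns[[i]]$image_id,
      width = anns[[i]]$width, height = anns[[i]]$height
    )
  })
  cat_id <- c(focal = 1L, gfp = 2L)
  annotations <- list()
  k <- 0L
  for (i in seq_along(anns)) {
    obj <- anns[[i]]$objects
    for (j in seq_len(nrow(obj))) {
      k <- k + 1L
      w <- obj$x_max[j] - obj$x_min[j]
      h <- obj$y_max[j] - obj$y_min[j]
      annotations[[k]] <- list(
        id = k, image_id = i, category_id = unname(cat_id[[obj$class[j]]]),
        bbox = c(obj$x_min[j], obj$y_min[j], w, h),
        area = w * h, iscrowd = 0L
      )
    }
  }
  categories <- list(
    list(id = 1L, name = "focal"),
    list(id = 2L, name = "gfp")
  )
  jsonlite::write_json(
    list(images = images, annotations = annotations, categories = categories),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
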