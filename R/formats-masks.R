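#' Write per-worm instance masks
#'
#' One binary image per worm, foreground = the worm's pixels, matching the
#' "one mask file per annotated object" layout of instance-segmentation
#' datasets. Masks are written as lossless PNG rather than JPEG because lossy
#' compression corrupts binary masks; [read_instance_mask()] remains tolerant
#' of legacy lossy masks by thresholding grey levels above 127/255.
#'
#' @param scene A `scene_truth` from [sample_scene()] (rasterised, i.e. with
#'   per-worm masks).
#' @param dir Output directory (created if absent).
#' @param which Indices of worms to write; defaults to all worms.
#' @return Character vector of written file paths, named
#'   `<image_id>_mask_<index>.png`, invisibly.
#' @export
write_instance_masks <- function(scene, dir, which = seq_along(scene$worms)) {
  stopifnot(inherits(scene, "scene_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in which) {
    w <- scene$worms[[i]]
    if (is.null(w$mask_idx)) {
      stop("scene was sampled without rasterisation; no mask for worm ", i)
    }
    if (any(w$mask_idx < 1L) || any(w$mask_idx > scene$height * scene$width)) {
      stop("mask indices of worm ", i, " fall outside the image")
    }
    m <- matrix(0, scene$height, scene$width)
    m[w$mask_idx] <- 1
    path <- file.path(dir, sprintf("%s_mask_%03d.png", scene$image_id, i))
    png::writePNG(m, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_instance_masks
#' @param path Path to a mask image (PNG, or TIFF if the `tiff` package is
#'   installed).
#' @return `read_instance_mask()` returns a logical matrix (rows = y,
#'   columns = x).
#' @export
read_instance_mask <- function(path) {
  img <- read_grayscale_image(path)
  img > 127 / 255
}

# Read a PNG/TIFF image as a grayscale matrix in [0, 1] (rows = y, cols = x).
read_grayscale_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L && !isTRUE(all.equal(img[, , 1], img[, , 2]))) {
      stop("image ", path, " is not grayscale")
    }
    img <- img[, , 1]
  }
  img
}
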