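#' Worm classes
#'
#' Exactly two classes exist in this assay: `"focal"` (the non-fluorescent
#' wild-type strain whose fitness is being estimated) and `"gfp"` (the
#' competitor tester strain with GFP expression restricted to the pharynx).
#' There is no "unknown" class: parsers either map every label to one of the
#' two or fail loudly.
#'
#' @return Character vector `c("focal", "gfp")`.
#' @export
worm_classes <- function() c("focal", "gfp")

#' Default mapping from annotation label strings to worm classes
#'
#' Published datasets do not standardise label strings, so the mapping from
#' the strings found in VOC/COCO files to the two internal classes is a
#' user-configurable named character vector (names = labels found in files,
#' values = `"focal"` or `"gfp"`). Matching is case-insensitive.
#'
#' @return Named character vector suitable for the `class_table` argument of
#'   the readers.
#' @export
default_class_table <- function() {
  c(
    "elegans" = "focal", "focal" = "focal", "non-gfp" = "focal",
    "non_gfp" = "focal", "wildtype" = "focal", "wild-type" = "focal",
    "gfp" = "gfp"
  )
}

map_class_names <- function(labels, class_table = default_class_table()) {
  names(class_table) <- tolower(names(class_table))
  mapped <- unname(class_table[tolower(labels)])
  bad <- unique(labels[is.na(mapped)])
  if (length(bad)) {
    stop(
      "unknown class name(s): ", paste(sQuote(bad), collapse = ", "),
      "; extend the class_table to map them to 'focal' or 'gfp'"
    )
  }
  mapped
}

empty_objects <- function() {
  data.frame(
    x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric(),
    class = character(), stringsAsFactors = FALSE
  )
}

empty_detections <- function() {
  data.frame(
    class = character(),
    x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric(),
    confidence = numeric(), stringsAsFactors = FALSE
  )
}

#' Ground-truth annotation for one image
#'
#' The ground-truth unit: an image identifier, the image size in pixels, and
#' a table of labelled objects (one row per worm: half-open box plus class).
#' By the edge-exclusion rule, annotations never contain objects whose mask
#' touches the image border; [scene_to_annotation()] enforces this for
#' synthetic scenes and the readers take files as given.
#'
#' @param image_id Character scalar identifying the image.
#' @param width,height Image size in pixels (> 0).
#' @param objects Data frame with columns `x_min`, `y_min`, `x_max`, `y_max`
#'   (0-based half-open) and `class` (`"focal"` or `"gfp"`). May have zero
#'   rows.
#' @return An object of class `worm_annotation`.
#' @export
worm_annotation <- function(image_id, width, height, objects = empty_objects()) {
  stopifnot(is.character(image_id), length(image_id) == 1L, width > 0, height > 0)
  objects <- as.data.frame(objects, stringsAsFactors = FALSE)
  if (nrow(objects)) {
    stopifnot(all(c("x_min", "y_min", "x_max", "y_max", "class") %in% names(objects)))
    if (any(objects$x_min >= objects$x_max) || any(objects$y_min >= objects$y_max)) {
      stop("degenerate box in annotation for image ", image_id)
    }
    if (any(objects$x_min < 0) || any(objects$y_min < 0) ||
        any(objects$x_max > width) || any(objects$y_max > height)) {
      stop("box outside image bounds in annotation for image ", image_id)
    }
    if (!all(objects$class %in% worm_classes())) {
      stop("object classes must be 'focal' or 'gfp'")
    }
  }
  rownames(objects) <- NULL
  structure(
    list(image_id = image_id, width = width, height = height, objects = objects),
    class = "worm_annotation"
  )
}

#' @export
print.worm_annotation <- function(x, ...) {
  cat(
    "<worm_annotation> image", x$image_id,
    sprintf("(%d x %d px), %d object(s):", x$width, x$height, nrow(x$objects)),
    "\n"
  )
  if (nrow(x$objects)) {
    tab <- table(factor(x$objects$class, levels = worm_classes()))
    cat("  focal:", tab[["focal"]], " gfp:", tab[["gfp"]], "\n")
  }
  invisible(x)
}

#' Detections for one image
#'
#' The evaluated unit: the detector's (or the perturbation model's) boxes for
#' one image, each with a class and a confidence score. All confidences must
#' be at or above `score_threshold`, mirroring a detector that only reports
#' objects whose class probability exceeds a predefined threshold.
#'
#' @param image_id Character scalar identifying the image.
#' @param detections Data frame with columns `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence`. May have zero rows.
#' @param score_threshold Confidence floor in \[0, 1\].
#' @return An object of class `worm_detections`.
#' @export
worm_detections <- function(image_id, detections = empty_detections(),
                            score_threshold = 0) {
  stopifnot(
    is.character(image_id), length(image_id) == 1L,
    score_threshold >= 0, score_threshold <= 1
  )
  detections <- as.data.frame(detections, stringsAsFactors = FALSE)
  if (nrow(detections)) {
    stopifnot(all(c("class", "x_min", "y_min", "x_max", "y_max", "confidence")
                  %in% names(detections)))
    if (!all(detections$class %in% worm_classes())) {
      stop("detection classes must be 'focal' or 'gfp'")
    }
    if (any(detections$confidence < 0 | detections$confidence > 1)) {
      stop("confidences must lie in [0, 1]")
    }
    if (any(detections$confidence < score_threshold)) {
      stop("all confidences must be >= score_threshold")
    }
    if (any(detections$x_min >= detections$x_max) ||
        any(detections$y_min >= detections$y_max)) {
      stop("degenerate box in detections for image ", image_id)
    }
  }
  detections <- detections[c("class", "x_min", "y_min", "x_max", "y_max", "confidence")]
  rownames(detections) <- NULL
  structure(
    list(
      image_id = image_id, detections = detections,
      score_threshold = score_threshold
    ),
    class = "worm_detections"
  )
}

#' @export
print.worm_detections <- function(x, ...) {
  cat(
    "<worm_detections> image", x$image_id, "-", nrow(x$detections),
    "detection(s), score threshold", x$score_threshold, "\n"
  )
  invisible(x)
}

# Per-image focal/gfp counts from an annotation or detection set.
count_classes <- function(x) {
  df <- if (inherits(x, "worm_annotation")) x$objects else x$detections
  tab <- table(factor(df$class, levels = worm_classes()))
  data.frame(
    image = x$image_id,
    focal = as.integer(tab[["focal"]]),
    gfp = as.integer(tab[["gfp"]]),
    stringsAsFactors = FALSE
  )
}
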