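#' Bounding-box geometry
#'
#' All boxes inside the package use one convention: 0-based, half-open pixel
#' rectangles, so a box covering the single pixel at (0, 0) is
#' `(x_min = 0, y_min = 0, x_max = 1, y_max = 1)` and
#' `area = (x_max - x_min) * (y_max - y_min)`. Conversions from the 1-based
#' inclusive Pascal VOC convention and the x/y/w/h COCO convention happen only
#' at the I/O boundary (see [read_voc_xml()], [read_coco_json()]).
#'
#' @param boxes A data frame with numeric columns `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @return `box_area()` returns a numeric vector of areas, one per row.
#' @examples
#' b <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' box_area(b) # 100
#' @export
box_area <- function(boxes) {
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

#' Intersection over union of two boxes
#'
#' @param a,b Numeric vectors `c(x_min, y_min, x_max, y_max)` or one-row data
#'   frames with those columns (half-open convention).
#' @return IoU in \[0, 1\]: the intersection area divided by the union area.
#'   Symmetric in its arguments; 0 for disjoint boxes.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 50 / 150
#' @export
box_iou <- function(a, b) {
  a <- as_box_vec(a)
  b <- as_box_vec(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  if (inter <= 0) return(0)
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

as_box_vec <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- c(x$x_min, x$y_min, x$x_max, x$y_max)
  }
  stopifnot(is.numeric(x), length(x) == 4L)
  if (x[1] >= x[3] || x[2] >= x[4]) {
    stop("invalid box: require x_min < x_max and y_min < y_max")
  }
  x
}

# Pairwise IoU matrix between two box data frames (n_a x n_b). Vectorised over
# the second argument; used by the matcher.
iou_matrix <- function(a, b) {
  na <- nrow(a)
  nb <- nrow(b)
  m <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(m)
  area_a <- box_area(a)
  area_b <- box_area(b)
  for (i in seq_len(na)) {
    ix <- pmax(0, pmin(a$x_max[i], b$x_max) - pmax(a$x_min[i], b$x_min))
    iy <- pmax(0, pmin(a$y_max[i], b$y_max) - pmax(a$y_min[i], b$y_min))
    inter <- ix * iy
    m[i, ] <- inter / (area_a[i] + area_b - inter)
  }
  m
}

#' Assign objects to MS-COCO-style size bins
#'
#' Objects are grouped into small / medium / large bins by pixel area (mask
#' area when available, otherwise box area). The default interpretation of
#' the COCO size groups uses side-length thresholds of 32 and 96 px, i.e.
#' areas of 32^2 = 1024 and 96^2 = 9216 px^2. A literal reading (areas of
#' 32 and 96 px^2) is available via `convention = "literal"`.
#'
#' @param area Numeric vector of object areas in px^2, or a box data frame
#'   (in which case box areas are used).
#' @param convention `"coco"` (default; thresholds 1024 and 9216 px^2) or
#'   `"literal"` (thresholds 32 and 96 px^2).
#' @return A factor with levels `small`, `medium`, `large`.
#' @examples
#' size_bin(c(400, 1600, 10000)) # small, medium, large
#' @export
size_bin <- function(area, convention = c("coco", "literal")) {
  convention <- match.arg(convention)
  if (is.data.frame(area)) area <- box_area(area)
  lims <- if (convention == "coco") c(1024, 9216) else c(32, 96)
  out <- ifelse(area < lims[1], "small", ifelse(area <= lims[2], "medium", "large"))
  factor(out, levels = c("small", "medium", "large"))
}
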