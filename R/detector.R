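#' Parameters of the classical reference detector
#'
#' A deterministic threshold-and-label detector that stands in for a trained
#' network so the whole pipeline can run end to end at desk scale. The
#' confidence it reports is an intensity heuristic (mean component intensity
#' over `worm_level`, clipped below at `confidence_floor`): classical
#' components have no learned score, so the value is arbitrary but monotone
#' in contrast.
#'
#' @param body_threshold `"otsu"` (default) or a fixed intensity in \[0, 1\]
#'   used to binarise the image.
#' @param min_area,max_area Component area filter in px^2.
#' @param pharynx_threshold Intensity above which a pixel counts as pharynx
#'   glow.
#' @param min_pharynx_pixels Minimum number of bright pixels for a component
#'   to be called GFP.
#' @param confidence_floor Lower clip of the reported confidence.
#' @param worm_level Expected body intensity used to normalise the
#'   confidence heuristic.
#' @param min_contrast Minimum separation between mean foreground and mean
#'   background intensity for the binarisation to be trusted; below it the
#'   image is declared objectless (guards against thresholding pure noise
#'   on blank images).
#' @return A validated list of class `detector_params`.
#' @export
detector_params <- function(body_threshold = "otsu",
                            min_area = 100, max_area = 50000,
                            pharynx_threshold = 0.7, min_pharynx_pixels = 5,
                            confidence_floor = 0.2, worm_level = 0.45,
                            min_contrast = 0.1) {
  p <- list(
    body_threshold = body_threshold, min_area = min_area, max_area = max_area,
    pharynx_threshold = pharynx_threshold,
    min_pharynx_pixels = as.integer(min_pharynx_pixels),
    confidence_floor = confidence_floor, worm_level = worm_level,
    min_contrast = min_contrast
  )
  if (!identical(p$body_threshold, "otsu")) {
    stopifnot(is.numeric(p$body_threshold),
              p$body_threshold >= 0, p$body_threshold <= 1)
  }
  stopifnot(
    p$min_area < p$max_area, p$min_area >= 0,
    p$pharynx_threshold >= 0, p$pharynx_threshold <= 1,
    p$min_pharynx_pixels >= 1,
    p$confidence_floor >= 0, p$confidence_floor <= 1, p$worm_level > 0,
    p$min_contrast >= 0
  )
  structure(p, class = "detector_params")
}

# 8-connected component labels: EBImage::bwlabel is 4-connected, so labels
# touching only diagonally are merged afterwards with a tiny union-find.
label_components_8 <- function(bw) {
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n < 2) return(lab)
  h <- nrow(lab)
  w <- ncol(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union_pairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    for (k in which(keep)) {
      ra <- find(a[k])
      rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  # diagonal neighbours: (r, c) vs (r+1, c+1) and (r+1, c) vs (r, c+1)
  union_pairs(lab[-h, -w], lab[-1, -1])
  union_pairs(lab[-1, -w], lab[-h, -1])
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  idx <- lab > 0
  lab[idx] <- relab[lab[idx]]
  lab
}

#' Detect worms in a grayscale image
#'
#' The classical pipeline: binarise (Otsu or fixed threshold), label
#' 8-connected components, filter by area, discard any component with a
#' border pixel (the edge-exclusion rule: edge animals are not fully
#' visible), then classify each remaining component as GFP iff at least
#' `min_pharynx_pixels` of its pixels exceed `pharynx_threshold`, else
#' focal. Touching or tangled worms are deliberately NOT split: a merged
#' component becomes a single detection, reproducing the dominant error
#' mode of detectors at high animal density.
#'
#' @param image Numeric matrix in \[0, 1\] (rows = y, columns = x), e.g.
#'   from [render_image()] or [read_grayscale_image()].
#' @param params A [detector_params()].
#' @param image_id Identifier for the returned detection set.
#' @return A [worm_detections()]; an image with no detectable objects gives
#'   an empty set, not an error.
#' @export
detect_worms <- function(image, params = detector_params(),
                         image_id = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric grayscale matrix")
  }
  stopifnot(inherits(params, "detector_params"))
  h <- nrow(image)
  w <- ncol(image)
  thr <- if (identical(params$body_threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    params$body_threshold
  }
  bw <- image > thr
  if (!any(bw) || all(bw) ||
      mean(image[bw]) - mean(image[!bw]) < params$min_contrast) {
    return(worm_detections(image_id, score_threshold = params$confidence_floor))
  }
  lab <- label_components_8(bw)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows0 <- (idx - 1L) %% h       # 0-based y
  cols0 <- (idx - 1L) %/% h      # 0-based x
  border_labs <- unique(labs[rows0 == 0L | rows0 == h - 1L |
                             cols0 == 0L | cols0 == w - 1L])
  areas <- tabulate(labs)
  keep <- setdiff(
    which(areas >= params$min_area & areas <= params$max_area),
    border_labs
  )
  if (!length(keep)) {
    return(worm_detections(image_id, score_threshold = params$confidence_floor))
  }
  dets <- do.call(rbind, lapply(keep, function(k) {
    sel <- labs == k
    xs <- cols0[sel]
    ys <- rows0[sel]
    vals <- image[idx[sel]]
    n_bright <- sum(vals > params$pharynx_threshold)
    data.frame(
      class = if (n_bright >= params$min_pharynx_pixels) "gfp" else "focal",
      x_min = min(xs), y_min = min(ys),
      x_max = max(xs) + 1, y_max = max(ys) + 1,
      confidence = min(1, max(params$confidence_floor,
                              mean(vals) / params$worm_level)),
      stringsAsFactors = FALSE
    )
  }))
  worm_detections(image_id, dets, score_threshold = params$confidence_floor)
}

#' Detect worms in a batch of images
#'
#' Runs [detect_worms()] on every image and assembles the per-image
#' focal/GFP count table (the same output contract as a trained detection
#' model: one CSV row per image with the class tallies). Per-image failures
#' are re-raised with the image id attached.
#'
#' @param images Named list of grayscale matrices (names become image ids).
#' @param params A [detector_params()].
#' @param counts_csv Optional path; when given, the count table is written
#'   there via [write_counts_csv()].
#' @param detections_csv Optional path for the full detection table.
#' @return A list: `detections` (named list of [worm_detections()]) and
#'   `counts` (data frame `image`, `focal`, `gfp`).
#' @export
detect_batch <- function(images, params = detector_params(),
                         counts_csv = NULL, detections_csv = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image%03d", seq_along(images))
  dets <- vector("list", length(images))
  for (i in seq_along(images)) {
    dets[[i]] <- tryCatch(
      detect_worms(images[[i]], params, image_id = ids[i]),
      error = function(e) {
        stop("image ", ids[i], ": ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  names(dets) <- ids
  counts <- do.call(rbind, lapply(dets, count_classes))
  rownames(counts) <- NULL
  if (!is.null(counts_csv)) write_counts_csv(counts, counts_csv)
  if (!is.null(detections_csv)) write_detections_csv(dets, detections_csv)
  list(detections = dets, counts = counts)
}
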