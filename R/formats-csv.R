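#' Per-image class-count tables
#'
#' The counting contract of the assay: one CSV row per image with the number
#' of focal and GFP animals, header `image,focal,gfp`. Duplicate image ids
#' are an error.
#'
#' @param counts Data frame with columns `image`, `focal`, `gfp`.
#' @param path File path.
#' @return `write_counts_csv()` returns `path` invisibly; `read_counts_csv()`
#'   returns the counts data frame.
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(all(c("image", "focal", "gfp") %in% names(counts)))
  if (anyDuplicated(counts$image)) {
    stop("duplicate image id(s) in counts: ",
         paste(unique(counts$image[duplicated(counts$image)]), collapse = ", "))
  }
  utils::write.csv(counts[c("image", "focal", "gfp")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image", "focal", "gfp") %in% names(counts)))
  if (anyDuplicated(counts$image)) {
    stop("duplicate image id(s) in counts file ", path)
  }
  counts
}

#' Detection tables
#'
#' Detections for a set of images are serialised as one CSV with header
#' `image,class,x_min,y_min,x_max,y_max,confidence`. Integer boxes round-trip
#' exactly.
#'
#' @param dets A [worm_detections()] or a list of them.
#' @param path File path.
#' @return `write_detections_csv()` returns `path` invisibly;
#'   `read_detections_csv()` returns a named list of [worm_detections()],
#'   one per image id present in the file.
#' @export
write_detections_csv <- function(dets, path) {
  if (inherits(dets, "worm_detections")) dets <- list(dets)
  rows <- lapply(dets, function(d) {
    stopifnot(inherits(d, "worm_detections"))
    if (nrow(d$detections) == 0L) return(NULL)
    cbind(image = d$image_id, d$detections)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(
      image = character(), class = character(),
      x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric(),
      confidence = numeric()
    )
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @param score_threshold Score threshold recorded on the re-read detection
#'   sets (the CSV itself does not carry one).
#' @export
read_detections_csv <- function(path, score_threshold = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "class", "x_min", "y_min", "x_max", "y_max", "confidence")
  stopifnot(all(need %in% names(df)))
  ids <- unique(df$image)
  out <- lapply(ids, function(id) {
    worm_detections(
      image_id = id,
      detections = df[df$image == id,
                      c("class", "x_min", "y_min", "x_max", "y_max", "confidence")],
      score_threshold = score_threshold
    )
  })
  names(out) <- ids
  out
}
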