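#' Five-way outcome classification of detections and annotations
#'
#' Assigns every detection and every annotated worm to exactly one outcome:
#' correct (matched, classes agree), incorrect class (matched, classes
#' disagree), counted twice (an extra detection overlapping an
#' already-claimed worm at or above the IoU threshold), missed (annotated
#' worm with no match), or false detection (detection overlapping no worm).
#'
#' Matching is deliberately class-AGNOSTIC here, unlike metric scoring: a
#' wrong-class detection sitting on a worm is one "incorrect count", not a
#' miss plus a false positive. When a detection could be several things the
#' precedence is primary-match classification, then counted twice, then
#' false detection; a duplicate with the wrong class is still counted twice
#' because the worm's classification is already decided by its primary
#' match.
#'
#' Two conservation identities always hold:
#' `correct + incorrect_class + missed = n_annotations` and
#' `correct + incorrect_class + counted_twice + false_detection =
#' n_detections`.
#'
#' @param dets A [worm_detections()].
#' @param ann A [worm_annotation()] for the same image.
#' @param iou_threshold IoU threshold (default 0.5).
#' @return A one-row data frame: `image`, `correct`, `incorrect_class`,
#'   `counted_twice`, `missed`, `false_detection`, `n_annotations`,
#'   `n_detections`.
#' @export
classify_outcomes <- function(dets, ann, iou_threshold = 0.5) {
  ms <- match_boxes(dets, ann, iou_threshold, class_aware = FALSE)
  d <- dets$detections
  a <- ann$objects
  correct <- incorrect <- 0L
  if (nrow(ms$pairs)) {
    agree <- d$class[ms$pairs$det] == a$class[ms$pairs$ann]
    correct <- sum(agree)
    incorrect <- sum(!agree)
  }
  counted_twice <- false_detection <- 0L
  for (di in ms$unmatched_detections) {
    overlaps <- nrow(a) > 0 && any(ms$iou[di, ] >= iou_threshold)
    if (overlaps) counted_twice <- counted_twice + 1L
    else false_detection <- false_detection + 1L
  }
  data.frame(
    image = ann$image_id,
    correct = correct, incorrect_class = incorrect,
    counted_twice = counted_twice,
    missed = length(ms$unmatched_annotations),
    false_detection = false_detection,
    n_annotations = nrow(a), n_detections = nrow(d),
    stringsAsFactors = FALSE
  )
}

#' Regress an outcome-category count on animal density
#'
#' Ordinary least squares of the per-image count of one outcome category on
#' the total number of annotated ("by eye") animals in the image,
#' `y = a + b x`. For a perfect detector the correct-count regression is
#' exactly `y = x` (slope 1, intercept 0); error categories of a detector
#' whose mistakes grow with animal clustering show small positive slopes.
#'
#' @param tallies Data frame of per-image tallies, as returned by
#'   [classify_outcomes()] (rbind-ed over images).
#' @param category One of `"correct"`, `"incorrect_class"`,
#'   `"counted_twice"`, `"missed"`, `"false_detection"`.
#' @return An `ols_fit` (see [ols_fit()]).
#' @export
error_density_regression <- function(tallies,
                                     category = c("correct", "incorrect_class",
                                                  "counted_twice", "missed",
                                                  "false_detection")) {
  category <- match.arg(category)
  stopifnot(all(c(category, "n_annotations") %in% names(tallies)))
  ols_fit(tallies$n_annotations, tallies[[category]])
}
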