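#' Greedy confidence-ordered matching of detections to annotations
#'
#' One-to-one assignment in the style of detection benchmarks: detections are
#' visited in decreasing confidence order (ties broken by the higher best
#' candidate IoU, then by lower detection index) and each claims the
#' still-unclaimed annotation with the highest IoU at or above
#' `iou_threshold` (restricted to the same class when `class_aware`).
#' Leftovers on both sides are reported unmatched.
#'
#' @param dets A [worm_detections()].
#' @param ann A [worm_annotation()] for the same image.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @param class_aware If `TRUE` (default) detections can only claim
#'   annotations of their own class; the class-agnostic variant is used by
#'   the error taxonomy.
#' @return A `match_set`: `pairs` (data frame `det`, `ann`, `iou`),
#'   `unmatched_detections`, `unmatched_annotations` (integer index
#'   vectors), `iou_threshold`, and the pairwise `iou` matrix.
#' @export
match_boxes <- function(dets, ann, iou_threshold = 0.5, class_aware = TRUE) {
  stopifnot(inherits(dets, "worm_detections"), inherits(ann, "worm_annotation"))
  d <- dets$detections
  a <- ann$objects
  nd <- nrow(d)
  na <- nrow(a)
  m <- iou_matrix(d, a)
  eligible <- m >= iou_threshold
  if (class_aware && nd && na) {
    eligible <- eligible & outer(d$class, a$class, "==")
  }
  best_iou <- if (na) apply(ifelse(eligible, m, -Inf), 1, max) else rep(-Inf, nd)
  ord <- order(-d$confidence, -best_iou, seq_len(nd))
  claimed <- rep(FALSE, na)
  pairs <- data.frame(det = integer(), ann = integer(), iou = numeric())
  for (di in ord) {
    cand <- which(eligible[di, ] & !claimed)
    if (!length(cand)) next
    ai <- cand[which.max(m[di, cand])]
    claimed[ai] <- TRUE
    pairs <- rbind(pairs, data.frame(det = di, ann = ai, iou = m[di, ai]))
  }
  structure(
    list(
      pairs = pairs,
      unmatched_detections = setdiff(seq_len(nd), pairs$det),
      unmatched_annotations = which(!claimed),
      n_detections = nd, n_annotations = na,
      iou_threshold = iou_threshold, class_aware = class_aware,
      iou = m
    ),
    class = "match_set"
  )
}

#' @export
print.match_set <- function(x, ...) {
  cat(
    "<match_set>", nrow(x$pairs), "pair(s),",
    length(x$unmatched_detections), "unmatched detection(s),",
    length(x$unmatched_annotations), "unmatched annotation(s) at IoU >=",
    x$iou_threshold, "\n"
  )
  invisible(x)
}

#' Precision and recall over one or more matched images
#'
#' True positives are matched pairs, false positives unmatched detections,
#' false negatives unmatched annotations: `precision = TP / (TP + FP)` and
#' `recall = TP / (TP + FN)`. With zero detections precision is undefined
#' and reported as `NA` with the counts intact; with zero annotations recall
#' is likewise `NA`.
#'
#' @param matches A `match_set` from [match_boxes()], or a list of them
#'   (counts are summed across images).
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
precision_recall <- function(matches) {
  if (inherits(matches, "match_set")) matches <- list(matches)
  stopifnot(all(vapply(matches, inherits, logical(1), "match_set")))
  tp <- sum(vapply(matches, function(m) nrow(m$pairs), integer(1)))
  fp <- sum(vapply(matches, function(m) length(m$unmatched_detections), integer(1)))
  fn <- sum(vapply(matches, function(m) length(m$unmatched_annotations), integer(1)))
  list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}
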