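# Per-class detection records across an image set: for every detection of
# `class`, its confidence and status (tp / fp / ignore), plus the number of
# positives. Annotations outside `bin` are "ignore" targets: detections
# matched to them count neither as TP nor FP (COCO-style size stratification).
collect_class_records <- function(ann_list, det_list, class,
                                  iou_threshold = 0.5, bin = NULL,
                                  convention = "coco") {
  conf <- numeric(0)
  status <- character(0)
  n_pos <- 0L
  for (i in seq_along(ann_list)) {
    ann <- ann_list[[i]]
    det <- det_list[[i]]
    a_keep <- which(ann$objects$class == class)
    d_keep <- which(det$detections$class == class)
    sub_ann <- worm_annotation(ann$image_id, ann$width, ann$height,
                               ann$objects[a_keep, , drop = FALSE])
    sub_det <- worm_detections(det$image_id,
                               det$detections[d_keep, , drop = FALSE],
                               det$score_threshold)
    in_bin <- if (is.null(bin)) {
      rep(TRUE, length(a_keep))
    } else {
      as.character(size_bin(sub_ann$objects, convention)) == bin
    }
    n_pos <- n_pos + sum(in_bin)
    ms <- match_boxes(sub_det, sub_ann, iou_threshold, class_aware = TRUE)
    st <- rep("fp", nrow(sub_det$detections))
    if (nrow(ms$pairs)) {
      st[ms$pairs$det] <- ifelse(in_bin[ms$pairs$ann], "tp", "ignore")
    }
    conf <- c(conf, sub_det$detections$confidence)
    status <- c(status, st)
  }
  list(confidence = conf, status = status, n_pos = n_pos)
}

ap_from_records <- function(rec) {
  if (rec$n_pos == 0L) return(NA_real_)
  keep <- rec$status != "ignore"
  conf <- rec$confidence[keep]
  tp <- rec$status[keep] == "tp"
  if (!length(conf)) return(0)
  ord <- order(-conf, seq_along(conf))
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec_curve <- cum_tp / rec$n_pos
  # all-point interpolation: p_interp(r) = max precision at recall >= r
  p_interp <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec_curve)) * p_interp)
}

ar_from_records <- function(rec) {
  if (rec$n_pos == 0L) return(NA_real_)
  sum(rec$status == "tp") / rec$n_pos
}

macro_average <- function(per_class, warn = TRUE) {
  defined <- !is.na(per_class)
  if (!any(defined)) return(NA_real_)
  if (warn && !all(defined)) {
    warning("class(es) without annotations excluded from the macro average: ",
            paste(names(per_class)[!defined], collapse = ", "))
  }
  mean(per_class[defined])
}

#' Average precision at a fixed IoU threshold
#'
#' Detections of each class are ranked by confidence across all images,
#' matched greedily per image, and swept from the top: the area under the
#' resulting precision-recall curve is computed with all-point
#' interpolation (`p_interp(r)` = max precision at recall >= `r`), the
#' convention of modern VOC-style evaluations. An 11-point variant is not
#' provided; the interpolation choice is documented in the methods vignette.
#'
#' @param ann_list,det_list Parallel lists of [worm_annotation()] and
#'   [worm_detections()] (same images, same order).
#' @param iou_threshold IoU threshold (default 0.5).
#' @return A list: `per_class` (named numeric, `NA` for a class with no
#'   annotations, excluded from the macro average with a warning) and
#'   `macro`.
#' @export
average_precision <- function(ann_list, det_list, iou_threshold = 0.5) {
  per_class <- vapply(worm_classes(), function(cl) {
    ap_from_records(collect_class_records(ann_list, det_list, cl, iou_threshold))
  }, numeric(1))
  list(per_class = per_class, macro = macro_average(per_class))
}

#' Average recall at a fixed IoU threshold
#'
#' The fraction of annotated worms of each class recovered by the retained
#' detections at the IoU threshold, with no per-image cap on the number of
#' detections, macro-averaged over classes.
#'
#' @inheritParams average_precision
#' @return A list: `per_class` and `macro`, as in [average_precision()].
#' @export
average_recall <- function(ann_list, det_list, iou_threshold = 0.5) {
  per_class <- vapply(worm_classes(), function(cl) {
    ar_from_records(collect_class_records(ann_list, det_list, cl, iou_threshold))
  }, numeric(1))
  list(per_class = per_class, macro = macro_average(per_class))
}

#' Detection metrics stratified by animal density and object size
#'
#' Images are split into two density strata by their ground-truth animal
#' count (`< density_threshold` vs `>= density_threshold`, default 70), and
#' within each stratum AP and AR are computed per MS-COCO-style size bin
#' (plus an "all" column), macro-averaged over the two classes. Cells whose
#' size bin contains no annotated animals are reported as `NA` with support
#' 0 (printed as "No animals" by [format_metrics_report()]).
#'
#' @inheritParams average_precision
#' @param density_threshold Ground-truth animal count separating the
#'   low-density from the high-density stratum.
#' @param size_convention Passed to [size_bin()].
#' @return A data frame with columns `stratum` (`low`/`high`), `n_images`,
#'   `size` (`small`/`medium`/`large`/`all`), `n_annotations`,
#'   `average_precision`, `average_recall`.
#' @export
stratified_report <- function(ann_list, det_list, iou_threshold = 0.5,
                              density_threshold = 70,
                              size_convention = c("coco", "literal")) {
  size_convention <- match.arg(size_convention)
  stopifnot(length(ann_list) == length(det_list))
  density <- vapply(ann_list, function(a) nrow(a$objects), integer(1))
  strata <- list(low = density < density_threshold,
                 high = density >= density_threshold)
  rows <- list()
  for (s in names(strata)) {
    idx <- which(strata[[s]])
    for (bin in c("small", "medium", "large", "all")) {
      if (!length(idx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, n_images = 0L, size = bin, n_annotations = 0L,
          average_precision = NA_real_, average_recall = NA_real_
        )
        next
      }
      bin_arg <- if (bin == "all") NULL else bin
      recs <- lapply(worm_classes(), function(cl) {
        collect_class_records(ann_list[idx], det_list[idx], cl, iou_threshold,
                              bin = bin_arg, convention = size_convention)
      })
      names(recs) <- worm_classes()
      ap <- vapply(recs, ap_from_records, numeric(1))
      ar <- vapply(recs, ar_from_records, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, n_images = length(idx), size = bin,
        n_annotations = sum(vapply(recs, `[[`, numeric(1), "n_pos")),
        average_precision = macro_average(ap, warn = FALSE),
        average_recall = macro_average(ar, warn = FALSE)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a stratified metrics report as aligned text
#'
#' Lays the report out with one row per metric and one column per size bin,
#' writing "No animals" for empty cells and "No images" for an empty
#' stratum.
#'
#' @param report Output of [stratified_report()].
#' @return A character scalar (multi-line).
#' @export
format_metrics_report <- function(report) {
  fmt_cell <- function(v, n) {
    if (n == 0L) "No animals" else sprintf("%.3f", v)
  }
  lines <- character(0)
  for (s in unique(report$stratum)) {
    sub <- report[report$stratum == s, ]
    label <- if (s == "low") "Low density" else "High density"
    lines <- c(lines, sprintf("%s (%d images)", label, sub$n_images[1]))
    if (sub$n_images[1] == 0L) {
      lines <- c(lines, "  No images", "")
      next
    }
    bins <- c("small", "medium", "large", "all")
    header <- sprintf("  %-28s %12s %12s %12s %12s", "Metric",
                      "Small", "Medium", "Large", "All")
    ap <- ar <- character(4)
    for (b in seq_along(bins)) {
      row <- sub[sub$size == bins[b], ]
      ap[b] <- fmt_cell(row$average_precision, row$n_annotations)
      ar[b] <- fmt_cell(row$average_recall, row$n_annotations)
    }
    lines <- c(
      lines, header,
      sprintf("  %-28s %12s %12s %12s %12s", "Average precision @ IoU=0.50",
              ap[1], ap[2], ap[3], ap[4]),
      sprintf("  %-28s %12s %12s %12s %12s", "Average recall @ IoU=0.50",
              ar[1], ar[2], ar[3], ar[4]),
      ""
    )
  }
  paste(lines, collapse = "\n")
}
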