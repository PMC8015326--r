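# A one-class image set with 2 annotations and the ranked detection pattern
# TP(conf .9), FP(conf .8), TP(conf .7) used across the AP tests.
ap_worked_example <- function() {
  ann <- worm_annotation("ap1", 300, 100, data.frame(
    x_min = c(10, 110), y_min = 10, x_max = c(40, 140), y_max = 40,
    class = "focal"
  ))
  det <- worm_detections("ap1", data.frame(
    class = "focal",
    x_min = c(10, 210, 110), y_min = c(10, 10, 10),
    x_max = c(40, 240, 140), y_max = c(40, 40, 40),
    confidence = c(0.9, 0.8, 0.7)
  ))
  list(ann = list(ann), det = list(det))
}

test_that("AP is 1 for perfect detections and 0 when all are false", {
  case <- withr::with_seed(11, random_eval_case(8, 0, 300, 300))
  perfect <- worm_detections("case", data.frame(
    class = case$ann$objects$class,
    case$ann$objects[c("x_min", "y_min", "x_max", "y_max")],
    confidence = withr::with_seed(1, runif(8, 0.5, 1))
  ))
  ap <- average_precision(list(case$ann), list(perfect))
  expect_equal(unname(ap$macro), 1)
  ar <- average_recall(list(case$ann), list(perfect))
  expect_equal(unname(ar$macro), 1)

  allfalse <- worm_detections("case", data.frame(
    class = "focal", x_min = 280, y_min = 280, x_max = 295, y_max = 295,
    confidence = 0.9
  ))
  onefocal <- worm_annotation("case", 300, 300, data.frame(
    x_min = 5, y_min = 5, x_max = 25, y_max = 25, class = "focal"
  ))
  ap0 <- suppressWarnings(average_precision(list(onefocal), list(allfalse)))
  expect_equal(ap0$per_class[["focal"]], 0)
})

test_that("the ranked TP/FP/TP example gives AP = 0.8333... and matches the sweep oracle", {
  ex <- ap_worked_example()
  ap <- suppressWarnings(average_precision(ex$ann, ex$det))
  expect_equal(ap$per_class[["focal"]], 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-12)
  # independent exhaustive threshold sweep
  expect_equal(
    ap$per_class[["focal"]],
    oracle_ap_sweep(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2L),
    tolerance = 1e-12
  )
  # gfp has no annotations: excluded from the macro average with a warning
  expect_warning(average_precision(ex$ann, ex$det), "gfp")
})

test_that("AP is invariant under strictly monotone confidence transforms", {
  withr::with_seed(21, {
    case <- random_eval_case(10, 12, 250, 250)
    ap1 <- suppressWarnings(average_precision(list(case$ann), list(case$det)))
    d2 <- case$det$detections
    d2$confidence <- plogis(5 * d2$confidence - 2)  # strictly increasing
    det2 <- worm_detections("case", d2)
    ap2 <- suppressWarnings(average_precision(list(case$ann), list(det2)))
    expect_equal(ap1$per_class, ap2$per_class, tolerance = 1e-12)
  })
})

test_that("AR uses all retained detections and bounds the AP sweep endpoint", {
  # half of the annotations matched -> AR = 0.5
  ann <- worm_annotation("ar1", 200, 100, data.frame(
    x_min = c(10, 110), y_min = 10, x_max = c(40, 140), y_max = 40,
    class = "focal"
  ))
  det <- worm_detections("ar1", data.frame(
    class = "focal", x_min = 10, y_min = 10, x_max = 40, y_max = 40,
    confidence = 0.6
  ))
  ar_half <- suppressWarnings(average_recall(list(ann), list(det)))
  expect_equal(ar_half$per_class[["focal"]], 0.5)
  ex <- ap_worked_example()
  ar <- suppressWarnings(average_recall(ex$ann, ex$det))$per_class[["focal"]]
  expect_gte(ar, 1.0)  # final-point recall of the sweep is 2/2
})

test_that("the stratified report splits at the density threshold and marks empty cells", {
  mk_image <- function(id, n) {
    x <- rep(seq(5, 960, by = 34), length.out = n)
    y <- rep(seq(5, 760, by = 40), each = 29, length.out = n)
    objects <- data.frame(x_min = x, y_min = y, x_max = x + 30, y_max = y + 36,
                          class = rep(c("focal", "gfp"), length.out = n))
    ann <- worm_annotation(id, 1024, 819, objects)
    det <- worm_detections(id, data.frame(
      class = objects$class, objects[c("x_min", "y_min", "x_max", "y_max")],
      confidence = 0.9
    ))
    list(ann = ann, det = det)
  }
  lo <- mk_image("lo", 60)
  hi <- mk_image("hi", 80)
  rep2 <- stratified_report(list(lo$ann, hi$ann), list(lo$det, hi$det),
                            density_threshold = 70)
  expect_equal(unique(rep2$stratum), c("low", "high"))
  expect_equal(rep2$n_images[rep2$stratum == "low"][1], 1L)
  expect_equal(rep2$n_images[rep2$stratum == "high"][1], 1L)
  # 30x36 boxes are medium; small and large cells are empty
  low <- rep2[rep2$stratum == "low", ]
  expect_equal(low$n_annotations[low$size == "small"], 0)
  expect_equal(low$n_annotations[low$size == "medium"], 60)
  expect_true(is.na(low$average_precision[low$size == "small"]))
  expect_equal(low$average_precision[low$size == "all"], 1)
  txt <- format_metrics_report(rep2)
  expect_match(txt, "No animals")

  # all images below threshold -> empty high stratum, no crash
  rep3 <- stratified_report(list(lo$ann), list(lo$det), density_threshold = 70)
  high <- rep3[rep3$stratum == "high", ]
  expect_true(all(high$n_images == 0L))
  expect_match(format_metrics_report(rep3), "No images")
})

test_that("a stratum with higher error rates scores lower AP", {
  cfg <- sim_config(n_worms = 40, image_width = 512, image_height = 400,
                    worm_length_range = c(40, 70), worm_width_range = c(6, 10),
                    cluster_fraction = 0, seed = 1)
  anns <- dets_lo <- dets_hi <- list()
  for (k in 1:6) {
    c2 <- cfg
    c2$seed <- 200L + k
    ann <- scene_to_annotation(sample_scene(c2, sprintf("i%d", k),
                                            rasterize = FALSE))
    anns[[k]] <- ann
    dets_lo[[k]] <- perturb_detections(ann, error_rates(0.02, 0, 0, 0, 0, 0.5),
                                       seed = k)
    dets_hi[[k]] <- perturb_detections(ann, error_rates(0.3, 0.1, 0.1, 0.05, 3, 2),
                                       seed = k)
  }
  ap_lo <- average_precision(anns, dets_lo)$macro
  ap_hi <- average_precision(anns, dets_hi)$macro
  expect_gt(ap_lo, ap_hi)
})
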