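small_cfg <- function(n_worms = 8, seed = 5, noise_sd = 0, ...) {
  sim_config(image_width = 300, image_height = 240, n_worms = n_worms,
             worm_length_range = c(40, 70), worm_width_range = c(6, 10),
             cluster_fraction = 0, noise_sd = noise_sd, seed = seed, ...)
}

test_that("scene sampling is deterministic and honours n_worms and classes", {
  cfg <- small_cfg(n_worms = 5, seed = 1)
  s1 <- sample_scene(cfg)
  s2 <- sample_scene(cfg)
  expect_length(s1$worms, 5L)
  expect_identical(s1, s2)
  # focal_fraction = 1 -> all focal
  all_focal <- sample_scene(small_cfg(focal_fraction = 1, seed = 2))
  expect_true(all(vapply(all_focal$worms, `[[`, character(1), "class") == "focal"))
  # geometry-only and rasterised sampling agree on worm identity
  fast <- sample_scene(cfg, rasterize = FALSE)
  expect_equal(
    vapply(fast$worms, `[[`, character(1), "class"),
    vapply(s1$worms, `[[`, character(1), "class")
  )
  expect_equal(
    vapply(fast$worms, `[[`, logical(1), "touches_edge"),
    vapply(s1$worms, `[[`, logical(1), "touches_edge")
  )
})

test_that("masks, boxes and edge flags are mutually consistent", {
  cfg <- small_cfg(n_worms = 12, seed = 42)
  scene <- sample_scene(cfg)
  h <- scene$height
  for (w in scene$worms) {
    kx <- (w$mask_idx - 1L) %/% h
    ky <- (w$mask_idx - 1L) %% h
    # box is the tight mask bounding box
    expect_equal(unname(w$box),
                 c(min(kx), min(ky), max(kx) + 1, max(ky) + 1))
    # edge flag iff the mask has a border pixel (clipped worms always do)
    on_border <- any(kx == 0 | kx == scene$width - 1 | ky == 0 | ky == h - 1)
    if (on_border) expect_true(w$touches_edge)
  }
})

test_that("scene_to_annotation applies the edge-exclusion rule exactly", {
  found <- FALSE
  for (seed in 1:20) {
    scene <- sample_scene(small_cfg(n_worms = 10, seed = seed))
    edge <- vapply(scene$worms, `[[`, logical(1), "touches_edge")
    ann <- scene_to_annotation(scene)
    expect_equal(nrow(ann$objects), sum(!edge))
    if (any(edge) && any(!edge)) found <- TRUE
  }
  expect_true(found)  # the sweep exercised mixed scenes
  # all worms interior -> all annotated; empty scene -> empty annotation
  interior <- sample_scene(small_cfg(n_worms = 0, seed = 1))
  expect_equal(nrow(scene_to_annotation(interior)$objects), 0L)
})

test_that("rendering puts worms above background, pharynx brightest, deterministically", {
  cfg <- small_cfg(n_worms = 6, focal_fraction = 0.5, noise_sd = 0.01, seed = 9)
  scene <- sample_scene(cfg)
  img1 <- render_image(scene, cfg)
  img2 <- render_image(scene, cfg)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  classes <- vapply(scene$worms, `[[`, character(1), "class")
  gfp <- which(classes == "gfp")
  focal <- which(classes == "focal")
  expect_true(length(gfp) > 0 && length(focal) > 0)
  max_gfp <- max(vapply(gfp, function(i) max(img1[scene$worms[[i]]$mask_idx]),
                        numeric(1)))
  max_focal <- max(vapply(focal, function(i) max(img1[scene$worms[[i]]$mask_idx]),
                          numeric(1)))
  expect_gt(max_gfp, max_focal)

  # empty scene: nothing above the illumination-modulated background + noise
  empty_cfg <- small_cfg(n_worms = 0, noise_sd = 0.01, seed = 3)
  bg <- render_image(sample_scene(empty_cfg), empty_cfg)
  cap <- empty_cfg$background_level *
    (1 + empty_cfg$illumination_gradient / 2) + 5 * empty_cfg$noise_sd
  expect_true(max(bg) <= cap)
})

test_that("annotated boxes enclose their worm's rendered pixels", {
  cfg <- small_cfg(n_worms = 8, focal_fraction = 0.4, seed = 21)
  scene <- sample_scene(cfg)
  ann <- scene_to_annotation(scene)
  idx <- attr(ann, "worm_index")
  h <- scene$height
  for (k in seq_along(idx)) {
    w <- scene$worms[[idx[k]]]
    kx <- (w$mask_idx - 1L) %/% h
    ky <- (w$mask_idx - 1L) %% h
    o <- ann$objects[k, ]
    expect_true(all(kx >= o$x_min & kx < o$x_max &
                    ky >= o$y_min & ky < o$y_max))
  }
})

test_that("perturbation with zero rates is the identity with IoU 1 per object", {
  cfg <- small_cfg(n_worms = 10, seed = 33)
  ann <- scene_to_annotation(sample_scene(cfg))
  det <- perturb_detections(ann, error_rates(0, 0, 0, 0, 0, 0), seed = 4)
  expect_equal(nrow(det$detections), nrow(ann$objects))
  ms <- match_boxes(det, ann, iou_threshold = 0.999)
  expect_equal(nrow(ms$pairs), nrow(ann$objects))
  expect_true(all(ms$pairs$iou == 1))
  expect_equal(det$detections$class, ann$objects$class)
  # miss_rate = 1 with no falses -> empty detection set
  none <- perturb_detections(ann, error_rates(1, 0, 0, 0, 0, 0), seed = 4)
  expect_equal(nrow(none$detections), 0L)
  # determinism
  expect_identical(det, perturb_detections(ann, error_rates(0, 0, 0, 0, 0, 0),
                                           seed = 4))
})

test_that("miss rate is recovered within binomial tolerance on 1000 objects", {
  objects <- data.frame(
    x_min = rep(seq(0, 900, by = 30), length.out = 1000) + 1,
    y_min = rep(seq(0, 700, by = 25), each = 31, length.out = 1000) + 1,
    class = "focal"
  )
  objects$x_max <- objects$x_min + 20
  objects$y_max <- objects$y_min + 15
  ann <- worm_annotation("big", 1024, 819, objects)
  det <- perturb_detections(ann, error_rates(0.1, 0, 0, 0, 0, 0), seed = 12)
  missed <- 1000 - nrow(det$detections)
  expect_lt(abs(missed - 100), 3 * sqrt(1000 * 0.1 * 0.9))
})

test_that("a simulated study has the study shape and is seed-reproducible", {
  cfg <- sim_config(n_worms = 12, seed = 2)
  st <- simulate_study(cfg, error_rates(), n_populations = c(1L, 1L),
                       parental_proportions = c(0.45, 0.75),
                       images_per_population = 2L, seed = 5)
  expect_length(st$populations, 2L)
  expect_equal(nrow(st$counts_eye), 4L)
  expect_equal(nrow(st$counts_model), 4L)
  st2 <- simulate_study(cfg, error_rates(), n_populations = c(1L, 1L),
                        parental_proportions = c(0.45, 0.75),
                        images_per_population = 2L, seed = 5)
  expect_identical(st$counts_model, st2$counts_model)
  expect_identical(st$populations[[1]]$true_p, st2$populations[[1]]$true_p)
})
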