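#' Detector error rates for the perturbation model
#'
#' Parameterises the corruption of ground truth into detector-like outputs.
#' Each rate drives one outcome category of the error taxonomy: `miss_rate`
#' drops worms (missed), the class-specific swap rates flip classes
#' (incorrect count), `duplicate_rate` double-fires on a worm (counted
#' twice), and `false_rate_per_image` is the expected Poisson count of
#' spurious boxes (false). `box_jitter_sd` adds Gaussian localisation noise
#' to every emitted box corner.
#'
#' The defaults describe a well-behaved detector making small, symmetric
#' errors of all five kinds; set everything to 0 for a perfect detector.
#'
#' @param miss_rate Per-worm drop probability.
#' @param swap_rate_gfp_to_focal,swap_rate_focal_to_gfp Per-worm class flip
#'   probabilities (applied to surviving worms of that class).
#' @param duplicate_rate Per-emitted-worm probability of a second jittered
#'   box on the same worm.
#' @param false_rate_per_image Expected number of spurious detections per
#'   image (Poisson).
#' @param box_jitter_sd SD of Gaussian jitter on box corners, px.
#' @return A validated list of class `error_rates`.
#' @export
error_rates <- function(miss_rate = 0.05,
                        swap_rate_gfp_to_focal = 0.02,
                        swap_rate_focal_to_gfp = 0.02,
                        duplicate_rate = 0.015,
                        false_rate_per_image = 0.5,
                        box_jitter_sd = 1) {
  rates <- list(
    miss_rate = miss_rate,
    swap_rate_gfp_to_focal = swap_rate_gfp_to_focal,
    swap_rate_focal_to_gfp = swap_rate_focal_to_gfp,
    duplicate_rate = duplicate_rate,
    false_rate_per_image = false_rate_per_image,
    box_jitter_sd = box_jitter_sd
  )
  probs <- unlist(rates[c("miss_rate", "swap_rate_gfp_to_focal",
                          "swap_rate_focal_to_gfp", "duplicate_rate")])
  stopifnot(
    all(probs >= 0), all(probs <= 1),
    rates$false_rate_per_image >= 0, rates$box_jitter_sd >= 0
  )
  structure(rates, class = "error_rates")
}

perfect_rates <- function() {
  error_rates(0, 0, 0, 0, 0, 0)
}

# Vectorised box jitter: each corner gets Gaussian noise, then boxes are
# re-ordered, clipped to the image, and degenerate boxes widened to 1 px.
jitter_boxes <- function(boxes, noise, sd, width, height) {
  if (sd > 0) boxes <- boxes + noise * sd
  fix_axis <- function(lo, hi, lim) {
    l <- pmin(lo, hi)
    u <- pmax(lo, hi)
    l <- pmin(pmax(l, 0), lim)
    u <- pmin(pmax(u, 0), lim)
    deg <- u - l < 1
    if (any(deg)) {
      l[deg] <- pmin(pmax(l[deg], 0), lim - 1)
      u[deg] <- l[deg] + 1
    }
    cbind(l, u)
  }
  x <- fix_axis(boxes[, 1], boxes[, 3], width)
  y <- fix_axis(boxes[, 2], boxes[, 4], height)
  cbind(x[, 1], y[, 1], x[, 2], y[, 2])
}

#' Corrupt ground truth into detector-like detections
#'
#' The inverse model of the five-way error taxonomy: each annotated worm is
#' independently dropped (missed), or emitted with its class flipped at the
#' class-specific swap rate and its box jittered; emitted worms double-fire
#' (a second jittered copy of the same box and class) with
#' `duplicate_rate`; finally `Poisson(false_rate_per_image)` spurious boxes
#' with random class are placed uniformly. Confidences are Uniform(0.5, 1)
#' for every detection, real or spurious, so confidence alone cannot
#' separate them. Deterministic given `seed`.
#'
#' @param ann A [worm_annotation()].
#' @param rates An [error_rates()].
#' @param seed Integer seed.
#' @return A [worm_detections()] with `score_threshold = 0.5`.
#' @export
perturb_detections <- function(ann, rates = error_rates(), seed = 1L) {
  stopifnot(inherits(ann, "worm_annotation"), inherits(rates, "error_rates"))
  withr::with_seed(child_seed(seed, 11L), {
    obj <- ann$objects
    n <- nrow(obj)
    w <- ann$width
    h <- ann$height
    u_miss <- stats::runif(n)
    u_swap <- stats::runif(n)
    noise <- matrix(stats::rnorm(4 * n), n, 4)
    u_dup <- stats::runif(n)
    noise_dup <- matrix(stats::rnorm(4 * n), n, 4)
    conf <- stats::runif(n, 0.5, 1)
    conf_dup <- stats::runif(n, 0.5, 1)

    keep <- u_miss >= rates$miss_rate
    swap_rate <- ifelse(obj$class == "gfp",
                        rates$swap_rate_gfp_to_focal,
                        rates$swap_rate_focal_to_gfp)
    cls <- ifelse(u_swap < swap_rate,
                  ifelse(obj$class == "gfp", "focal", "gfp"),
                  obj$class)
    boxes0 <- cbind(obj$x_min, obj$y_min, obj$x_max, obj$y_max)
    parts <- list()
    if (any(keep)) {
      jb <- jitter_boxes(boxes0[keep, , drop = FALSE],
                         noise[keep, , drop = FALSE],
                         rates$box_jitter_sd, w, h)
      parts$primary <- data.frame(
        class = cls[keep], x_min = jb[, 1], y_min = jb[, 2],
        x_max = jb[, 3], y_max = jb[, 4], confidence = conf[keep],
        stringsAsFactors = FALSE
      )
      # duplicates: a second jittered box on the same worm (the way a
      # detector double-fires), same emitted class
      dup <- keep & u_dup < rates$duplicate_rate
      if (any(dup)) {
        jd <- jitter_boxes(boxes0[dup, , drop = FALSE],
                           noise_dup[dup, , drop = FALSE],
                           max(rates$box_jitter_sd, 0.5), w, h)
        parts$duplicate <- data.frame(
          class = cls[dup], x_min = jd[, 1], y_min = jd[, 2],
          x_max = jd[, 3], y_max = jd[, 4], confidence = conf_dup[dup],
          stringsAsFactors = FALSE
        )
      }
    }
    n_false <- stats::rpois(1, rates$false_rate_per_image)
    if (n_false > 0) {
      # spurious boxes take worm-like sizes: sampled from the annotated
      # objects when present, otherwise from a generic size range
      if (n > 0) {
        src <- sample.int(n, n_false, replace = TRUE)
        bw <- boxes0[src, 3] - boxes0[src, 1]
        bh <- boxes0[src, 4] - boxes0[src, 2]
      } else {
        bw <- stats::runif(n_false, 20, 80)
        bh <- stats::runif(n_false, 20, 80)
      }
      bw <- pmin(bw, w - 1)
      bh <- pmin(bh, h - 1)
      x0 <- stats::runif(n_false, 0, w - bw)
      y0 <- stats::runif(n_false, 0, h - bh)
      parts$false <- data.frame(
        class = sample(worm_classes(), n_false, replace = TRUE),
        x_min = x0, y_min = y0, x_max = x0 + bw, y_max = y0 + bh,
        confidence = stats::runif(n_false, 0.5, 1),
        stringsAsFactors = FALSE
      )
    }
    dets <- if (length(parts)) do.call(rbind, parts) else empty_detections()
    worm_detections(ann$image_id, dets, score_threshold = 0.5)
  })
}

#' Simulate a full competitive fitness study
#'
#' Generates an annotation-level dataset shaped like a multi-population
#' competition experiment: populations are split across parental focal
#' proportions (defaults: 15, 15 and 25 populations at parental proportions
#' 0.45, 0.60 and 0.75, i.e. 550 images in total at 10 images per
#' population). Each population draws a true offspring focal fraction from a
#' Beta distribution centred on its parental proportion (concentration
#' `offspring_concentration`), then yields `images_per_population` scenes
#' whose worms share that fraction; detections are obtained by perturbing
#' the ground truth with `rates`. The "by eye" scores are the annotation
#' counts themselves.
#'
#' @param config A [sim_config()]; `config$n_worms` is used as the mean of
#'   the per-image Poisson worm count.
#' @param rates An [error_rates()] for the perturbation stage.
#' @param n_populations Integer vector, populations per treatment.
#' @param parental_proportions Parental focal proportions, one per treatment.
#' @param images_per_population Images (slide fields) per population.
#' @param offspring_concentration Beta concentration of the true offspring
#'   fraction around the parental proportion.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param rasterize Passed to [sample_scene()]; the default `FALSE` keeps
#'   study simulation at annotation level (no pixel masks).
#' @param image_dir If non-`NULL`, scenes are rasterised, rendered with
#'   [render_image()] and written as PNG files into this directory.
#' @return A `sim_study` list: `populations` (per population: id, parental
#'   and true focal proportion, annotations and detections per image) plus
#'   tidy count tables `counts_eye` and `counts_model` with columns
#'   `image`, `focal`, `gfp`, `population`.
#' @export
simulate_study <- function(config = sim_config(), rates = error_rates(),
                           n_populations = c(15L, 15L, 25L),
                           parental_proportions = c(0.45, 0.60, 0.75),
                           images_per_population = 10L,
                           offspring_concentration = 30,
                           seed = config$seed, rasterize = FALSE,
                           image_dir = NULL) {
  if (!is.null(image_dir)) {
    rasterize <- TRUE
    if (!dir.exists(image_dir)) dir.create(image_dir, recursive = TRUE)
  }
  stopifnot(
    length(n_populations) == length(parental_proportions),
    all(n_populations >= 1), all(parental_proportions >= 0),
    all(parental_proportions <= 1), images_per_population >= 1
  )
  pop_parental <- rep(parental_proportions, times = n_populations)
  n_pop <- length(pop_parental)
  populations <- vector("list", n_pop)
  counts_eye <- counts_model <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    pp <- pop_parental[i]
    draw <- withr::with_seed(child_seed(seed, i, 0L), {
      a <- pp * offspring_concentration
      b <- (1 - pp) * offspring_concentration
      true_p <- if (a == 0) 0 else if (b == 0) 1 else stats::rbeta(1, a, b)
      n_img <- stats::rpois(images_per_population, config$n_worms)
      list(true_p = true_p, n_img = n_img)
    })
    pop_id <- sprintf("pop%02d", i)
    anns <- dets <- vector("list", images_per_population)
    for (j in seq_len(images_per_population)) {
      img_id <- sprintf("%s_img%02d", pop_id, j)
      cfg <- config
      cfg$n_worms <- draw$n_img[j]
      cfg$focal_fraction <- draw$true_p
      cfg$seed <- child_seed(seed, i, j)
      scene <- sample_scene(cfg, image_id = img_id, rasterize = rasterize)
      if (!is.null(image_dir)) {
        png::writePNG(render_image(scene, cfg),
                      file.path(image_dir, paste0(img_id, ".png")))
      }
      anns[[j]] <- scene_to_annotation(scene)
      dets[[j]] <- perturb_detections(anns[[j]], rates,
                                      seed = child_seed(seed, i, j, 99L))
    }
    names(anns) <- names(dets) <- vapply(anns, `[[`, character(1), "image_id")
    populations[[i]] <- list(
      population_id = pop_id, parental_p = pp, true_p = draw$true_p,
      annotations = anns, detections = dets
    )
    ce <- do.call(rbind, lapply(anns, count_classes))
    cm <- do.call(rbind, lapply(dets, count_classes))
    ce$population <- cm$population <- pop_id
    counts_eye[[i]] <- ce
    counts_model[[i]] <- cm
  }
  structure(
    list(
      populations = populations,
      counts_eye = do.call(rbind, counts_eye),
      counts_model = do.call(rbind, counts_model),
      config = config, rates = rates, seed = seed
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(
    "<sim_study>", length(x$populations), "population(s),",
    nrow(x$counts_eye), "image(s)\n"
  )
  invisible(x)
}
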