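# Deterministic seed derivation: one user-facing seed expands into per-stage,
# per-image child seeds so adding images does not reshuffle existing ones.
# Mixing is a simple LCG-style fold kept below 2^31 (R integers are 32-bit).
child_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(h)
}

#' Configuration of the synthetic scene generator
#'
#' Defaults describe the imaging setup the generator emulates: 1024 x 819 px
#' grayscale fluorescence micrographs of L1/L2 larvae on a dark background,
#' with tens of worms per image, a fraction of them aggregated into clusters,
#' and GFP animals carrying a bright pharynx spot at one end of the body.
#'
#' @param image_width,image_height Image size in px.
#' @param n_worms Number of worms placed in the scene.
#' @param focal_fraction Probability that a worm is focal (non-GFP).
#' @param worm_length_range,worm_width_range Body length and full width in px
#'   (uniformly sampled per worm).
#' @param curvature_range Dimensionless bend: the middle control point is
#'   offset perpendicular to the body axis by `curvature * length`.
#' @param cluster_fraction Share of worms placed around shared cluster
#'   centres (Neyman-Scott-style parent/offspring placement); the remainder
#'   are placed uniformly.
#' @param cluster_radius Offspring displacement scale around a cluster
#'   centre, px.
#' @param min_separation If > 0, uniformly placed worms are re-drawn until
#'   their bounding boxes are at least this many px from all previously
#'   placed worms (used to build well-separated fixtures; 0 disables it).
#' @param pharynx_radius Radius of the GFP pharynx disk, px.
#' @param pharynx_gain Intensity multiplier of the pharynx over the body
#'   level (clipped to 1 at render time).
#' @param background_level,worm_level Background and body intensities in
#'   \[0, 1\]; `worm_level` must exceed `background_level`.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param illumination_gradient Relative magnitude of a linear illumination
#'   field across the image width: the multiplicative field spans
#'   `1 - g/2` to `1 + g/2`.
#' @param seed Integer seed; together with the config it fully determines
#'   every sampled scene.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(image_width = 1024, image_height = 819,
                       n_worms = 50, focal_fraction = 0.6,
                       worm_length_range = c(80, 160),
                       worm_width_range = c(8, 14),
                       curvature_range = c(0.05, 0.35),
                       cluster_fraction = 0.3, cluster_radius = 60,
                       min_separation = 0,
                       pharynx_radius = 6, pharynx_gain = 2,
                       background_level = 0.08, worm_level = 0.45,
                       noise_sd = 0.02, illumination_gradient = 0.15,
                       seed = 1L) {
  cfg <- list(
    image_width = image_width, image_height = image_height,
    n_worms = as.integer(n_worms), focal_fraction = focal_fraction,
    worm_length_range = worm_length_range, worm_width_range = worm_width_range,
    curvature_range = curvature_range,
    cluster_fraction = cluster_fraction, cluster_radius = cluster_radius,
    min_separation = min_separation,
    pharynx_radius = pharynx_radius, pharynx_gain = pharynx_gain,
    background_level = background_level, worm_level = worm_level,
    noise_sd = noise_sd, illumination_gradient = illumination_gradient,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$image_width > 0, cfg$image_height > 0, cfg$n_worms >= 0,
    cfg$focal_fraction >= 0, cfg$focal_fraction <= 1,
    all(cfg$worm_length_range > 0), all(cfg$worm_width_range > 0),
    diff(cfg$worm_length_range) >= 0, diff(cfg$worm_width_range) >= 0,
    cfg$cluster_fraction >= 0, cfg$cluster_fraction <= 1,
    cfg$cluster_radius > 0, cfg$min_separation >= 0,
    cfg$pharynx_radius > 0, cfg$pharynx_gain >= 1,
    cfg$background_level >= 0, cfg$background_level <= 1,
    cfg$worm_level <= 1, cfg$noise_sd >= 0,
    cfg$illumination_gradient >= 0
  )
  if (cfg$worm_level <= cfg$background_level) {
    stop("worm_level must exceed background_level (no contrast)")
  }
  diag_len <- sqrt(cfg$image_width^2 + cfg$image_height^2)
  if (max(cfg$worm_length_range) > diag_len) {
    stop("worm length exceeds the image diagonal")
  }
  structure(cfg, class = "sim_config")
}

# Quadratic Bezier through three control rows of `ctrl` at parameter values t.
bezier_points <- function(ctrl, t) {
  w0 <- (1 - t)^2
  w1 <- 2 * t * (1 - t)
  w2 <- t^2
  cbind(
    w0 * ctrl[1, 1] + w1 * ctrl[2, 1] + w2 * ctrl[3, 1],
    w0 * ctrl[1, 2] + w1 * ctrl[2, 2] + w2 * ctrl[3, 2]
  )
}

disk_offsets <- function(r) {
  rc <- ceiling(r)
  g <- expand.grid(dx = -rc:rc, dy = -rc:rc)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

# Rasterise one worm tube (plus optional pharynx disk) into 0-based pixel
# coordinates; returns body/pharynx pixel sets before clipping.
rasterize_worm <- function(ctrl, half_width, len, pharynx_centre, pharynx_radius) {
  m <- max(30L, ceiling(2 * len))
  pts <- bezier_points(ctrl, seq(0, 1, length.out = m))
  px <- round(pts[, 1])
  py <- round(pts[, 2])
  off <- disk_offsets(half_width)
  body <- unique(data.frame(
    x = rep(px, each = nrow(off)) + off$dx,
    y = rep(py, each = nrow(off)) + off$dy
  ))
  pharynx <- NULL
  if (!is.null(pharynx_centre)) {
    offp <- disk_offsets(pharynx_radius)
    pharynx <- unique(data.frame(
      x = round(pharynx_centre[1]) + offp$dx,
      y = round(pharynx_centre[2]) + offp$dy
    ))
  }
  list(body = body, pharynx = pharynx)
}

pixels_to_idx <- function(px, py, width, height) {
  keep <- px >= 0 & px < width & py >= 0 & py < height
  sort(unique(py[keep] + 1L + px[keep] * height))
}

#' Sample a synthetic worm scene
#'
#' Places `n_worms` smoothly curved worm tubes (quadratic splines through
#' three control points, thickened to half the sampled body width) in the
#' image. A `cluster_fraction` share of worms is aggregated around shared
#' cluster centres, emulating the tangling seen at high animal density; the
#' rest are uniform. Each worm is GFP with probability
#' `1 - focal_fraction`; GFP worms carry a pharynx disk at one body end.
#' Worms may overlap, and worms near the border may extend past it; those are
#' flagged `touches_edge` and excluded by [scene_to_annotation()].
#'
#' The scene is a pure function of `(config, config$seed)`.
#'
#' @param config A [sim_config()].
#' @param image_id Identifier attached to the scene and its annotation.
#' @param rasterize If `TRUE` (default), per-worm pixel masks are computed
#'   and boxes/edge flags are exact mask properties; if `FALSE`, boxes and
#'   edge flags come from the continuous tube geometry (much faster; used
#'   for annotation-level studies that never render images).
#' @return A `scene_truth`: image size, id, and a list of worms, each with
#'   control points, half-width, class, pharynx end, pixel mask (when
#'   rasterised), tight bounding box and `touches_edge` flag.
#' @export
sample_scene <- function(config, image_id = "scene", rasterize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$image_width
  h <- config$image_height
  n <- config$n_worms

  draws <- withr::with_seed(config$seed, {
    clustered <- stats::runif(n) < config$cluster_fraction
    n_centers <- max(1L, ceiling(sum(clustered) / 6))
    centers <- cbind(
      stats::runif(n_centers, 0.15 * w, 0.85 * w),
      stats::runif(n_centers, 0.15 * h, 0.85 * h)
    )
    center_of <- sample.int(n_centers, n, replace = TRUE)
    len <- stats::runif(n, config$worm_length_range[1], config$worm_length_range[2])
    half_width <- stats::runif(n, config$worm_width_range[1], config$worm_width_range[2]) / 2
    curv <- stats::runif(n, config$curvature_range[1], config$curvature_range[2])
    theta <- stats::runif(n, 0, 2 * pi)
    bend <- sample(c(-1, 1), n, replace = TRUE)
    pharynx_end <- sample(1:2, n, replace = TRUE)
    is_gfp <- stats::runif(n) >= config$focal_fraction
    midx <- ifelse(clustered,
                   centers[center_of, 1] + stats::rnorm(n, 0, config$cluster_radius / 2),
                   stats::runif(n, 0, w))
    midy <- ifelse(clustered,
                   centers[center_of, 2] + stats::rnorm(n, 0, config$cluster_radius / 2),
                   stats::runif(n, 0, h))
    midx <- pmin(pmax(midx, 0), w - 1)
    midy <- pmin(pmax(midy, 0), h - 1)
    extra <- if (config$min_separation > 0) {
      # re-draw candidate midpoints for the separation rejection loop
      matrix(stats::runif(2 * 200 * n), ncol = 2)
    } else NULL
    list(clustered = clustered, len = len, half_width = half_width,
         curv = curv, theta = theta, bend = bend, pharynx_end = pharynx_end,
         is_gfp = is_gfp, midx = midx, midy = midy, extra = extra)
  })

  worm_geometry <- function(i, mx, my) {
    d <- c(cos(draws$theta[i]), sin(draws$theta[i]))
    p <- c(-d[2], d[1]) * draws$bend[i]
    L <- draws$len[i]
    ctrl <- rbind(
      c(mx, my) - d * L / 2,
      c(mx, my) + p * draws$curv[i] * L,
      c(mx, my) + d * L / 2
    )
    ctrl
  }

  worm_extent <- function(ctrl, i) {
    pts <- bezier_points(ctrl, seq(0, 1, length.out = 25))
    r <- draws$half_width[i]
    ext <- c(min(pts[, 1]) - r, min(pts[, 2]) - r,
             max(pts[, 1]) + r, max(pts[, 2]) + r)
    if (draws$is_gfp[i]) {
      e <- if (draws$pharynx_end[i] == 1L) pts[1, ] else pts[25, ]
      pr <- config$pharynx_radius
      ext <- c(pmin(ext[1:2], e - pr), pmax(ext[3:4], e + pr))
    }
    ext
  }

  # Midpoints: optionally enforce a minimum box separation for uniform worms.
  mids <- cbind(draws$midx, draws$midy)
  if (config$min_separation > 0 && n > 0) {
    accepted <- matrix(numeric(0), ncol = 4)
    k <- 0L
    for (i in seq_len(n)) {
      for (try in 0:199) {
        if (try > 0L) {
          k <- k + 1L
          mids[i, ] <- c(draws$extra[k, 1] * w, draws$extra[k, 2] * h)
        }
        ext <- worm_extent(worm_geometry(i, mids[i, 1], mids[i, 2]), i)
        s <- config$min_separation
        ok <- nrow(accepted) == 0L || all(
          ext[1] - s > accepted[, 3] | ext[3] + s < accepted[, 1] |
          ext[2] - s > accepted[, 4] | ext[4] + s < accepted[, 2]
        )
        if (ok) break
      }
      accepted <- rbind(accepted, ext)
    }
  }

  worms <- vector("list", n)
  for (i in seq_len(n)) {
    ctrl <- worm_geometry(i, mids[i, 1], mids[i, 2])
    cls <- if (draws$is_gfp[i]) "gfp" else "focal"
    if (rasterize) {
      pts_end <- NULL
      if (draws$is_gfp[i]) {
        ends <- bezier_points(ctrl, c(0, 1))
        pts_end <- ends[draws$pharynx_end[i], ]
      }
      ras <- rasterize_worm(ctrl, draws$half_width[i], draws$len[i],
                            pts_end, config$pharynx_radius)
      allpx <- rbind(ras$body, ras$pharynx)
      touches <- any(allpx$x <= 0 | allpx$x >= w - 1 |
                     allpx$y <= 0 | allpx$y >= h - 1)
      body_idx <- pixels_to_idx(ras$body$x, ras$body$y, w, h)
      pharynx_idx <- if (is.null(ras$pharynx)) integer(0) else {
        pixels_to_idx(ras$pharynx$x, ras$pharynx$y, w, h)
      }
      mask_idx <- sort(unique(c(body_idx, pharynx_idx)))
      kx <- (mask_idx - 1L) %/% h
      ky <- (mask_idx - 1L) %% h
      box <- c(x_min = min(kx), y_min = min(ky),
               x_max = max(kx) + 1, y_max = max(ky) + 1)
      worms[[i]] <- list(
        control = ctrl, half_width = draws$half_width[i], class = cls,
        pharynx_end = draws$pharynx_end[i],
        body_idx = body_idx, pharynx_idx = pharynx_idx, mask_idx = mask_idx,
        box = box, touches_edge = touches
      )
    } else {
      ext <- worm_extent(ctrl, i)
      pmin_x <- round(ext[1]); pmin_y <- round(ext[2])
      pmax_x <- round(ext[3]); pmax_y <- round(ext[4])
      touches <- pmin_x <= 0 || pmin_y <= 0 ||
        pmax_x >= w - 1 || pmax_y >= h - 1
      box <- c(x_min = max(0, pmin_x), y_min = max(0, pmin_y),
               x_max = min(w, pmax_x + 1), y_max = min(h, pmax_y + 1))
      worms[[i]] <- list(
        control = ctrl, half_width = draws$half_width[i], class = cls,
        pharynx_end = draws$pharynx_end[i],
        body_idx = NULL, pharynx_idx = NULL, mask_idx = NULL,
        box = box, touches_edge = touches
      )
    }
  }

  structure(
    list(image_id = image_id, width = w, height = h, worms = worms,
         config = config),
    class = "scene_truth"
  )
}

#' @export
print.scene_truth <- function(x, ...) {
  n_edge <- sum(vapply(x$worms, `[[`, logical(1), "touches_edge"))
  cat(
    "<scene_truth>", x$image_id,
    sprintf("(%d x %d px): %d worm(s), %d touching the border\n",
            x$width, x$height, length(x$worms), n_edge)
  )
  invisible(x)
}

#' Derive the ground-truth annotation of a scene
#'
#' Applies the edge-exclusion rule: worms whose mask (or geometric extent,
#' for non-rasterised scenes) touches the image border are not annotated,
#' because an off-frame pharynx would make the class unknowable. Boxes are
#' the tight bounding boxes of the worm masks.
#'
#' @param scene A `scene_truth` from [sample_scene()].
#' @return A [worm_annotation()] containing exactly the non-edge worms, with
#'   attribute `worm_index` giving each object's index into `scene$worms`.
#' @export
scene_to_annotation <- function(scene) {
  stopifnot(inherits(scene, "scene_truth"))
  keep <- which(!vapply(scene$worms, `[[`, logical(1), "touches_edge"))
  objects <- if (length(keep)) {
    boxes <- t(vapply(scene$worms[keep], `[[`, numeric(4), "box"))
    data.frame(
      x_min = boxes[, "x_min"], y_min = boxes[, "y_min"],
      x_max = boxes[, "x_max"], y_max = boxes[, "y_max"],
      class = vapply(scene$worms[keep], `[[`, character(1), "class"),
      stringsAsFactors = FALSE
    )
  } else {
    empty_objects()
  }
  ann <- worm_annotation(scene$image_id, scene$width, scene$height, objects)
  attr(ann, "worm_index") <- keep
  ann
}

#' Render a scene as a grayscale fluorescence image
#'
#' Background sits at `background_level`, modulated by a linear illumination
#' field across the width (relative magnitude `illumination_gradient`), with
#' additive Gaussian noise of SD `noise_sd`. Worm bodies are drawn at
#' `worm_level`; each GFP worm carries a pharynx disk at
#' `min(1, worm_level * pharynx_gain)`. The result is clipped to \[0, 1\]
#' and is a pure function of `(scene, config)` (noise uses a child seed of
#' `config$seed`).
#'
#' @param scene A rasterised `scene_truth`.
#' @param config The [sim_config()] used to sample the scene.
#' @return A numeric matrix (`image_height` x `image_width`) in \[0, 1\];
#'   rows index y, columns x.
#' @export
render_image <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "scene_truth"), inherits(config, "sim_config"))
  w <- scene$width
  h <- scene$height
  grad <- 1 + config$illumination_gradient *
    ((seq_len(w) - 1) / max(1, w - 1) - 0.5)
  img <- matrix(rep(config$background_level * grad, each = h), h, w)
  for (worm in scene$worms) {
    if (is.null(worm$body_idx)) {
      stop("scene was sampled with rasterize = FALSE; cannot render")
    }
    img[worm$body_idx] <- config$worm_level
  }
  pharynx_level <- min(1, config$worm_level * config$pharynx_gain)
  for (worm in scene$worms) {
    if (worm$class == "gfp" && length(worm$pharynx_idx)) {
      img[worm$pharynx_idx] <- pharynx_level
    }
  }
  if (config$noise_sd > 0) {
    noise <- withr::with_seed(
      child_seed(config$seed, 7L),
      stats::rnorm(length(img), 0, config$noise_sd)
    )
    img <- img + noise
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}
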