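#' Full fitness comparison of model and by-eye count tables
#'
#' The analysis layer of the assay, run on two per-image count tables (one
#' scored by a detection model, one by eye) plus an image-to-population
#' map: per-image proportions and their differences, pooled per-population
#' estimates, method-bias regressions of the proportion difference on the
#' by-eye proportion at both the image and the population level, and the
#' variability comparison (paired Wilcoxon tests and SD-vs-proportion
#' regressions).
#'
#' @param counts_model,counts_eye Data frames with columns `image`,
#'   `focal`, `gfp` (see [read_counts_csv()]); they must cover the same
#'   images.
#' @param population_map Data frame with columns `image`, `population`.
#' @param drop_undefined_images If `TRUE` (default), images empty under
#'   either method are dropped from the image-level difference analysis
#'   (their counts still enter the pooled population sums).
#' @return A list of class `fitness_analysis`: `images` (per-image table
#'   with `p_model`, `p_eye`, `d`), `populations` (per-population table),
#'   `bias_image` and `bias_population` (`ols_fit`s of `d` on `p_eye`),
#'   and `variability` (see [variability_comparison()]).
#' @export
fitness_analysis <- function(counts_model, counts_eye, population_map,
                             drop_undefined_images = TRUE) {
  stopifnot(
    all(c("image", "focal", "gfp") %in% names(counts_model)),
    all(c("image", "focal", "gfp") %in% names(counts_eye)),
    all(c("image", "population") %in% names(population_map))
  )
  if (!setequal(counts_model$image, counts_eye$image)) {
    stop("the two count tables cover different images")
  }
  ord <- population_map$image
  if (!setequal(ord, counts_eye$image)) {
    stop("population map and count tables cover different images")
  }
  m <- counts_model[match(ord, counts_model$image), ]
  e <- counts_eye[match(ord, counts_eye$image), ]
  images <- data.frame(
    image = ord,
    population = population_map$population,
    focal_model = m$focal, gfp_model = m$gfp,
    focal_eye = e$focal, gfp_eye = e$gfp,
    stringsAsFactors = FALSE
  )
  tot_m <- images$focal_model + images$gfp_model
  tot_e <- images$focal_eye + images$gfp_eye
  images$p_model <- ifelse(tot_m > 0, images$focal_model / tot_m, NA_real_)
  images$p_eye <- ifelse(tot_e > 0, images$focal_eye / tot_e, NA_real_)
  images$d <- images$p_model - images$p_eye

  usable <- !is.na(images$d)
  if (!drop_undefined_images && any(!usable)) {
    stop(sum(!usable), " image(s) are empty under at least one method")
  }
  bias_image <- bias_analysis(images$p_eye[usable], images$d[usable])

  pops <- unique(images$population)
  pops_model <- pops_eye <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    sel <- images$population == pops[i]
    pops_model[[i]] <- population_estimate(
      data.frame(focal = images$focal_model[sel], gfp = images$gfp_model[sel]),
      population_id = pops[i], source = "model"
    )
    pops_eye[[i]] <- population_estimate(
      data.frame(focal = images$focal_eye[sel], gfp = images$gfp_eye[sel]),
      population_id = pops[i], source = "by_eye"
    )
  }
  variability <- variability_comparison(pops_model, pops_eye)
  ptab <- variability$table
  ptab$d <- ptab$pooled_p_model - ptab$pooled_p_eye
  bias_population <- bias_analysis(ptab$pooled_p_eye, ptab$d)

  structure(
    list(
      images = images, populations = ptab,
      bias_image = bias_image, bias_population = bias_population,
      variability = variability
    ),
    class = "fitness_analysis"
  )
}

#' @export
print.fitness_analysis <- function(x, ...) {
  cat("<fitness_analysis>", nrow(x$images), "image(s),",
      nrow(x$populations), "population(s)\n")
  cat(sprintf("  image-level bias slope      b = %+.4f (df = %d, P = %.4g)\n",
              x$bias_image$b, x$bias_image$df, x$bias_image$p_value))
  cat(sprintf("  population-level bias slope b = %+.4f (df = %d, P = %.4g)\n",
              x$bias_population$b, x$bias_population$df,
              x$bias_population$p_value))
  cat(sprintf("  Wilcoxon proportions P = %.4f, proportion SDs P = %.4f\n",
              x$variability$wilcoxon_proportions$p_value,
              x$variability$wilcoxon_sds$p_value))
  invisible(x)
}
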