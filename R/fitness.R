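#' Focal proportion of a count pair
#'
#' The fitness measure of the assay: the proportion of focal (non-GFP)
#' animals among all animals in one image,
#' `p = n_focal / (n_focal + n_gfp)`. An image with no animals yields an
#' explicitly undefined estimate (`p = NA`) carrying the counts, never a
#' silent 0/0.
#'
#' @param n_focal,n_gfp Non-negative counts.
#' @param source `"model"` or `"by_eye"`: which scoring method produced the
#'   counts.
#' @param image_id Optional image identifier.
#' @return A `fitness_estimate`: list with `p`, `n_focal`, `n_gfp`,
#'   `n_total`, `defined`, `source`, `image_id`.
#' @export
focal_proportion <- function(n_focal, n_gfp, source = c("model", "by_eye"),
                             image_id = NULL) {
  source <- match.arg(source)
  stopifnot(n_focal >= 0, n_gfp >= 0)
  total <- n_focal + n_gfp
  structure(
    list(
      p = if (total > 0) n_focal / total else NA_real_,
      n_focal = n_focal, n_gfp = n_gfp, n_total = total,
      defined = total > 0, source = source, image_id = image_id
    ),
    class = "fitness_estimate"
  )
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(
    "<fitness_estimate>", x$source, "p =",
    if (x$defined) sprintf("%.4f", x$p) else "undefined (no animals)",
    sprintf("(%d focal / %d total)\n", x$n_focal, x$n_total)
  )
  invisible(x)
}

#' Pooled population-level fitness estimate
#'
#' The population proportion is computed by summing focal and GFP counts
#' over all images of the population before dividing (never by averaging
#' per-image proportions; the two differ whenever image totals vary). Its
#' variability is the sample standard deviation (n - 1 denominator) of the
#' per-image proportions. Images with no animals are excluded from the
#' per-image proportions (and recorded in `n_excluded`), but their zero
#' counts still enter the pooled sums.
#'
#' @param counts Data frame with columns `focal` and `gfp` (one row per
#'   image), e.g. a slice of a counts table from [read_counts_csv()].
#' @param population_id Optional population identifier.
#' @param source `"model"` or `"by_eye"`.
#' @return A `population_estimate`: `pooled_p`, `per_image_p`, `sd_p`
#'   (`NA` when fewer than 2 defined images), `n_images`, `n_excluded`,
#'   `source`, `population_id`.
#' @export
population_estimate <- function(counts, population_id = NULL,
                                source = c("model", "by_eye")) {
  source <- match.arg(source)
  stopifnot(all(c("focal", "gfp") %in% names(counts)), nrow(counts) >= 1)
  totals <- counts$focal + counts$gfp
  if (sum(totals) == 0) {
    stop("all images of population ", population_id %||% "", " are empty")
  }
  defined <- totals > 0
  per_image_p <- counts$focal[defined] / totals[defined]
  structure(
    list(
      population_id = population_id,
      pooled_p = sum(counts$focal) / sum(totals),
      per_image_p = per_image_p,
      sd_p = if (length(per_image_p) >= 2) stats::sd(per_image_p) else NA_real_,
      n_images = nrow(counts), n_excluded = sum(!defined),
      source = source
    ),
    class = "population_estimate"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.population_estimate <- function(x, ...) {
  cat(
    "<population_estimate>", x$population_id %||% "", x$source,
    sprintf("pooled p = %.4f, sd of %d image proportions = %s\n",
            x$pooled_p, length(x$per_image_p),
            if (is.na(x$sd_p)) "NA" else sprintf("%.4f", x$sd_p))
  )
  invisible(x)
}

#' Proportion difference between the two scoring methods
#'
#' `d = p_model - p_eye` for the same image or population: positive values
#' mean the model over-estimates the focal proportion relative to the
#' by-eye score. Both estimates must be defined and come from different
#' sources.
#'
#' @param p_model A `fitness_estimate` with `source = "model"`.
#' @param p_eye A `fitness_estimate` with `source = "by_eye"`.
#' @return The difference, a number in \[-1, 1\].
#' @export
proportion_difference <- function(p_model, p_eye) {
  stopifnot(
    inherits(p_model, "fitness_estimate"),
    inherits(p_eye, "fitness_estimate")
  )
  if (p_model$source == p_eye$source) {
    stop("both estimates come from source '", p_model$source,
         "'; need one model and one by-eye estimate")
  }
  if (p_model$source != "model") {
    stop("first argument must be the model estimate")
  }
  if (!p_model$defined || !p_eye$defined) {
    stop("proportion difference of undefined estimate(s)")
  }
  p_model$p - p_eye$p
}

#' Simple linear regression y = a + b x
#'
#' Ordinary least squares with the usual t-test on the slope (df = n - 2)
#' and R-squared, as fitted by [stats::lm()]. When `y` is constant the fit
#' is the flat line (`b = 0`) and R-squared is reported as 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must not be
#'   constant.
#' @return An `ols_fit`: list with intercept `a`, slope `b`, their standard
#'   errors `se_a` and `se_b`, the slope's `t` and two-sided `p_value`
#'   (df = n - 2), `df`, `r_squared`, `n`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a regression")
  if (stats::var(x) == 0) stop("singular fit: x is constant")
  fit <- stats::lm(y ~ x)
  # perfect fits (e.g. a flawless detector giving y = x exactly) are a
  # legitimate fixed point here, not a modelling accident
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      a = unname(co[1, 1]), b = unname(co[2, 1]),
      se_a = unname(co[1, 2]), se_b = unname(co[2, 2]),
      t = if (ss_tot > 0) unname(co[2, 3]) else 0,
      p_value = if (ss_tot > 0) unname(co[2, 4]) else 1,
      df = n - 2L,
      r_squared = if (ss_tot > 0) sm$r.squared else 0,
      n = n
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "<ols_fit> y = %.4f + %.4f x  (SE_b = %.4f, t = %.3f, df = %d, P = %.4g, R^2 = %.3f)\n",
    x$a, x$b, x$se_b, x$t, x$df, x$p_value, x$r_squared
  ))
  invisible(x)
}

#' Method-bias regression of proportion differences
#'
#' Regresses the proportion difference `d = p_model - p_eye` on the by-eye
#' proportion (taken as the most reliable estimate of the true focal
#' proportion), at either the image or the population level. A negative
#' slope means the model biases small true proportions upward and large
#' ones downward; under a one-way GFP-to-focal class swap at rate `s` with
#' no other errors, `E(d) = s (1 - p)`, so the fitted slope and intercept
#' recover `-s` and `+s`.
#'
#' @param p_eye Numeric vector of by-eye proportions.
#' @param d Numeric vector of proportion differences (model minus eye).
#' @return An `ols_fit` of `d` on `p_eye`.
#' @export
bias_analysis <- function(p_eye, d) {
  ols_fit(p_eye, d)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the nonzero paired differences (zeros dropped,
#' Wilcoxon's original convention; ties receive midranks). The null
#' distribution is enumerated exactly (over all sign assignments, via a
#' convolution on the doubled midranks) when the number of nonzero
#' differences is at most `exact_max`, and approximated by a normal with
#' tie correction and continuity correction above that. Two-sided p-values
#' throughout, computed as `min(1, 2 min(P(W <= w), P(W >= w)))` for the
#' positive-rank sum `W`. When all pairs are equal there is no signal and
#' the p-value is 1 by convention (so pipelines on perfect agreement do not
#' crash).
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_max Largest number of nonzero differences for which the
#'   exact null distribution is enumerated (default 25).
#' @return A `wilcoxon_result`: `statistic` (positive-rank sum `W`),
#'   `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_paired <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(
      list(statistic = 0, p_value = 1, n_effective = 0L,
           method = "no nonzero differences"),
      class = "wilcoxon_result"
    ))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # distribution of the doubled positive-rank sum over all 2^n sign
    # assignments, by convolution
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    counts <- counts / 2^n
    w2 <- round(2 * W)
    p_le <- sum(counts[seq_len(w2 + 1L)])
    p_ge <- sum(counts[seq.int(w2 + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(
    list(statistic = W, p_value = p, n_effective = n, method = method),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "<wilcoxon_result> W = %g, n_effective = %d, P = %.4f (%s)\n",
    x$statistic, x$n_effective, x$p_value, x$method
  ))
  invisible(x)
}

#' Compare the variability of the two scoring methods
#'
#' For populations scored by both the model and by eye: paired Wilcoxon
#' tests on the pooled proportions and on their per-image SDs across
#' populations, plus a per-method regression of SD on pooled proportion
#' (binomial sampling makes SD peak near p = 0.5, so a moderate
#' relationship is expected).
#'
#' @param pops_model,pops_eye Lists of `population_estimate` objects with
#'   matching `population_id`s, one scored by the model and one by eye.
#' @return A list: `table` (per-population pooled p and sd for both
#'   methods), `wilcoxon_proportions`, `wilcoxon_sds`,
#'   `regression_model`, `regression_eye` (each an `ols_fit` of sd on
#'   pooled p).
#' @export
variability_comparison <- function(pops_model, pops_eye) {
  stopifnot(
    length(pops_model) == length(pops_eye), length(pops_model) >= 2,
    all(vapply(pops_model, inherits, logical(1), "population_estimate")),
    all(vapply(pops_eye, inherits, logical(1), "population_estimate"))
  )
  ids_m <- vapply(pops_model, function(p) p$population_id %||% NA_character_,
                  character(1))
  ids_e <- vapply(pops_eye, function(p) p$population_id %||% NA_character_,
                  character(1))
  if (!all(is.na(ids_m)) && !identical(ids_m, ids_e)) {
    stop("population ids of the two methods do not match")
  }
  tab <- data.frame(
    population = ids_m,
    pooled_p_model = vapply(pops_model, `[[`, numeric(1), "pooled_p"),
    pooled_p_eye = vapply(pops_eye, `[[`, numeric(1), "pooled_p"),
    sd_p_model = vapply(pops_model, `[[`, numeric(1), "sd_p"),
    sd_p_eye = vapply(pops_eye, `[[`, numeric(1), "sd_p"),
    stringsAsFactors = FALSE
  )
  list(
    table = tab,
    wilcoxon_proportions = wilcoxon_paired(tab$pooled_p_model, tab$pooled_p_eye),
    wilcoxon_sds = wilcoxon_paired(tab$sd_p_model, tab$sd_p_eye),
    regression_model = ols_fit(tab$pooled_p_model, tab$sd_p_model),
    regression_eye = ols_fit(tab$pooled_p_eye, tab$sd_p_eye)
  )
}
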