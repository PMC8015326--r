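#' Resolved configuration of a pipeline run
#'
#' Bundles every knob of a full simulate - detect/perturb - evaluate -
#' errors - fitness run. A serialised copy of the resolved config is
#' written as `config.json` into every output directory, and one global
#' seed expands into per-stage, per-image child seeds by a fixed rule.
#'
#' @param sim A [sim_config()].
#' @param rates An [error_rates()] for the perturbation stage.
#' @param detector A [detector_params()] for the classical detection stage.
#' @param n_populations,parental_proportions,images_per_population Study
#'   shape passed to [simulate_study()].
#' @param iou_threshold,density_threshold,size_convention Evaluation
#'   options.
#' @param render If `TRUE`, the simulate stage also renders and writes PNG
#'   images (required by the `detect` stage).
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), rates = error_rates(),
                       detector = detector_params(),
                       n_populations = c(15L, 15L, 25L),
                       parental_proportions = c(0.45, 0.60, 0.75),
                       images_per_population = 10L,
                       iou_threshold = 0.5, density_threshold = 70,
                       size_convention = "coco",
                       render = FALSE, seed = 1L) {
  structure(
    list(
      sim = sim, rates = rates, detector = detector,
      n_populations = as.integer(n_populations),
      parental_proportions = parental_proportions,
      images_per_population = as.integer(images_per_population),
      iou_threshold = iou_threshold, density_threshold = density_threshold,
      size_convention = size_convention,
      render = render, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

stage_input <- function(stage, path) {
  if (!file.exists(path)) {
    stop("stage '", stage, "': missing input ", path, call. = FALSE)
  }
  path
}

read_annotation_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  anns <- lapply(files, read_voc_xml)
  names(anns) <- vapply(anns, `[[`, character(1), "image_id")
  anns
}

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages: `simulate` (synthetic study: VOC annotations, by-eye counts,
#' population map, optionally rendered PNG images), `perturb` (corrupt
#' ground truth into detections) or `detect` (classical detector on the
#' rendered images), `evaluate` (density/size-stratified AP/AR grid),
#' `errors` (five-way tallies and density regressions) and `fitness`
#' (proportions, bias and variability analyses). Every stage reads its
#' inputs from `out_dir` and writes CSV outputs back, so any stage can be
#' re-run from the previous stage's files alone. The run is deterministic
#' given `config$seed`; a manifest of all outputs with MD5 hashes is
#' written at the end.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "perturb", "detect", "evaluate", "errors", "fitness")`.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = c("simulate", "perturb", "evaluate",
                                    "errors", "fitness")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "perturb", "detect", "evaluate", "errors",
                  "fitness")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    ann_dir = file.path(out_dir, "annotations"),
    img_dir = file.path(out_dir, "images"),
    counts_eye = file.path(out_dir, "counts_eye.csv"),
    counts_model = file.path(out_dir, "counts_model.csv"),
    pop_map = file.path(out_dir, "population_map.csv"),
    detections = file.path(out_dir, "detections.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    metrics_txt = file.path(out_dir, "metrics.txt"),
    tallies = file.path(out_dir, "error_tallies.csv"),
    error_reg = file.path(out_dir, "error_regressions.csv"),
    fit_images = file.path(out_dir, "fitness_images.csv"),
    fit_pops = file.path(out_dir, "fitness_populations.csv"),
    fit_tests = file.path(out_dir, "fitness_tests.csv")
  )

  if ("simulate" %in% stages) {
    study <- simulate_study(
      config$sim, config$rates,
      n_populations = config$n_populations,
      parental_proportions = config$parental_proportions,
      images_per_population = config$images_per_population,
      seed = child_seed(config$seed, 1L),
      image_dir = if (config$render) paths$img_dir else NULL
    )
    if (!dir.exists(paths$ann_dir)) dir.create(paths$ann_dir)
    for (pop in study$populations) {
      for (ann in pop$annotations) {
        write_voc_xml(ann, file.path(paths$ann_dir, paste0(ann$image_id, ".xml")))
      }
    }
    write_counts_csv(study$counts_eye, paths$counts_eye)
    utils::write.csv(
      data.frame(image = study$counts_eye$image,
                 population = study$counts_eye$population),
      paths$pop_map, row.names = FALSE, quote = FALSE
    )
  }

  if ("perturb" %in% stages) {
    anns <- read_annotation_dir(stage_input("perturb", paths$ann_dir))
    dets <- vector("list", length(anns))
    for (i in seq_along(anns)) {
      dets[[i]] <- perturb_detections(anns[[i]], config$rates,
                                      seed = child_seed(config$seed, 2L, i))
    }
    names(dets) <- names(anns)
    write_detections_csv(dets, paths$detections)
    counts <- do.call(rbind, lapply(dets, count_classes))
    write_counts_csv(counts, paths$counts_model)
  }

  if ("detect" %in% stages) {
    img_files <- sort(list.files(stage_input("detect", paths$img_dir),
                                 pattern = "\\.(png|tif|tiff)$",
                                 full.names = TRUE))
    if (!length(img_files)) {
      stop("stage 'detect': no images found in ", paths$img_dir)
    }
    images <- lapply(img_files, read_grayscale_image)
    names(images) <- tools::file_path_sans_ext(basename(img_files))
    detect_batch(images, config$detector,
                 counts_csv = paths$counts_model,
                 detections_csv = paths$detections)
  }

  if ("evaluate" %in% stages || "errors" %in% stages) {
    anns <- read_annotation_dir(stage_input("evaluate", paths$ann_dir))
    det_sets <- read_detections_csv(stage_input("evaluate", paths$detections))
    dets <- lapply(names(anns), function(id) {
      det_sets[[id]] %||% worm_detections(id)
    })
    names(dets) <- names(anns)
  }

  if ("evaluate" %in% stages) {
    report <- stratified_report(
      anns, dets, iou_threshold = config$iou_threshold,
      density_threshold = config$density_threshold,
      size_convention = config$size_convention
    )
    utils::write.csv(report, paths$metrics, row.names = FALSE, quote = FALSE)
    writeLines(format_metrics_report(report), paths$metrics_txt)
  }

  if ("errors" %in% stages) {
    tallies <- do.call(rbind, lapply(names(anns), function(id) {
      classify_outcomes(dets[[id]], anns[[id]], config$iou_threshold)
    }))
    utils::write.csv(tallies, paths$tallies, row.names = FALSE, quote = FALSE)
    cats <- c("correct", "incorrect_class", "counted_twice", "missed",
              "false_detection")
    regs <- do.call(rbind, lapply(cats, function(ct) {
      fit <- tryCatch(error_density_regression(tallies, ct),
                      error = function(e) NULL)
      if (is.null(fit)) {
        data.frame(category = ct, a = NA, b = NA, se_b = NA, t = NA,
                   p_value = NA, df = NA, r_squared = NA)
      } else {
        data.frame(category = ct, a = fit$a, b = fit$b, se_b = fit$se_b,
                   t = fit$t, p_value = fit$p_value, df = fit$df,
                   r_squared = fit$r_squared)
      }
    }))
    utils::write.csv(regs, paths$error_reg, row.names = FALSE, quote = FALSE)
  }

  if ("fitness" %in% stages) {
    counts_model <- read_counts_csv(stage_input("fitness", paths$counts_model))
    counts_eye <- read_counts_csv(stage_input("fitness", paths$counts_eye))
    pop_map <- utils::read.csv(stage_input("fitness", paths$pop_map),
                               stringsAsFactors = FALSE)
    fa <- fitness_analysis(counts_model, counts_eye, pop_map)
    utils::write.csv(fa$images, paths$fit_images, row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(fa$populations, paths$fit_pops, row.names = FALSE,
                     quote = FALSE)
    tests <- rbind(
      ols_row("bias_image", fa$bias_image),
      ols_row("bias_population", fa$bias_population),
      ols_row("sd_vs_p_model", fa$variability$regression_model),
      ols_row("sd_vs_p_eye", fa$variability$regression_eye),
      wilcox_row("wilcoxon_proportions", fa$variability$wilcoxon_proportions),
      wilcox_row("wilcoxon_sds", fa$variability$wilcoxon_sds)
    )
    utils::write.csv(tests, paths$fit_tests, row.names = FALSE, quote = FALSE)
  }

  jsonlite::write_json(
    unclass_deep(config), file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  files <- setdiff(
    list.files(out_dir, recursive = TRUE),
    "manifest.csv"
  )
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

ols_row <- function(name, fit) {
  data.frame(
    test = name, statistic = fit$b, se = fit$se_b, df = fit$df,
    p_value = fit$p_value, r_squared = fit$r_squared,
    stringsAsFactors = FALSE
  )
}

wilcox_row <- function(name, wr) {
  data.frame(
    test = name, statistic = wr$statistic, se = NA_real_,
    df = wr$n_effective, p_value = wr$p_value, r_squared = NA_real_,
    stringsAsFactors = FALSE
  )
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Human-readable summary of a pipeline output directory
#'
#' Assembles one markdown report from whatever stage outputs are present:
#' the stratified metrics grid, the error-slope table, the bias regression
#' lines, and the variability comparison. Missing outputs are marked as
#' gaps rather than errors; an empty directory yields an explicit
#' "no outputs" message. Regenerating the report is deterministic.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @param file Optional path to also write the report to (default
#'   `report.md` inside `out_dir`; `NULL` to skip writing).
#' @return The report text as a character scalar, invisibly.
#' @export
pipeline_report <- function(out_dir, file = file.path(out_dir, "report.md")) {
  lines <- c("# Pipeline report", "")
  found <- FALSE
  p <- function(...) file.path(out_dir, ...)
  if (file.exists(p("metrics.txt"))) {
    found <- TRUE
    lines <- c(lines, "## Detection metrics", "",
               readLines(p("metrics.txt")), "")
  } else {
    lines <- c(lines, "## Detection metrics", "", "(not computed)", "")
  }
  if (file.exists(p("error_regressions.csv"))) {
    found <- TRUE
    regs <- utils::read.csv(p("error_regressions.csv"))
    lines <- c(lines, "## Error-count regressions on animal density", "",
               "category | slope | SE | P", "---|---|---|---",
               sprintf("%s | %.4f | %.4f | %.4g",
                       regs$category, regs$b, regs$se_b, regs$p_value), "")
  } else {
    lines <- c(lines, "## Error-count regressions", "", "(not computed)", "")
  }
  if (file.exists(p("fitness_tests.csv"))) {
    found <- TRUE
    tests <- utils::read.csv(p("fitness_tests.csv"))
    fmt <- sprintf("%s | %.4f | %s | %.4g",
                   tests$test, tests$statistic,
                   ifelse(is.na(tests$se), "-", sprintf("%.4f", tests$se)),
                   tests$p_value)
    lines <- c(lines, "## Fitness comparison", "",
               "test | statistic | SE | P", "---|---|---|---", fmt, "")
  } else {
    lines <- c(lines, "## Fitness comparison", "", "(not computed)", "")
  }
  if (!found) lines <- c("# Pipeline report", "", "No outputs found in ",
                         out_dir)
  text <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(text, file)
  invisible(text)
}
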