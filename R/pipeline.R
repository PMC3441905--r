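#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end ECV pipeline with their
#' defaults, serializable losslessly to YAML.  A hash of the configuration
#' is recorded in every report so outputs are traceable to their settings.
#'
#' @param ... overrides as nested lists, e.g.
#'   `pipeline_config(moco = list(n_iterations = 3))`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    moco = list(enabled = TRUE, n_iterations = 2, tol_px = 0.5),
    coreg = list(enabled = TRUE),
    registration = list(sigma_field = 4, sigma_fluid = 1, n_levels = 3,
                        max_iter = 50, tol = 0.01, step_cap = 1),
    segmentation = list(threshold_ms = 1250, min_component = 10,
                        erosion_radius = 1, min_pixels = 20),
    fit = list(t1_starts = c(150, 400, 800, 1500)),
    seed = 1L)
  overrides <- list(...)
  for (nm in names(overrides))
    cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_config` returns a `pipeline_config`; `write_config` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[names(raw) != "seed"]) -> cfg
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

reg_params_from_config <- function(config) do.call(reg_params, config$registration)

sig6 <- function(x) signif(x, 6)

#' Run the automated ECV pipeline end to end
#'
#' Reads the pre- and post-contrast MOLLI series, motion-corrects each
#' breath-hold, co-registers the post-contrast series to the pre-contrast
#' frame, fits the final T1 maps, segments the blood pool on the
#' pre-contrast T1 map, computes the ECV map calibrated by hematocrit, and
#' writes all artifacts plus a JSON report to `out_dir`.  Without a
#' hematocrit the ECV stage is skipped and a partition-coefficient map is
#' produced instead, with a warning.
#'
#' @param pre_path,post_path `.nii` paths (with TI sidecars; see
#'   [read_series()]) or [molli_series()] objects.
#' @param hematocrit venous hematocrit (fraction or percent string), or
#'   `NULL`.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param verbose log stage progress and timings.
#' @return Invisibly, a list with the in-memory results: `pre_moco`,
#'   `post_moco`, `coreg`, `pre_fit`, `post_fit`, `blood`, `ecv` (or
#'   `lambda`), and `report`.
#' @export
run_pipeline <- function(pre_path, post_path, hematocrit = NULL,
                         out_dir = ".", config = pipeline_config(),
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("[%s] done in %.1f s", name,
                      proc.time()[["elapsed"]] - t0))
    res
  }
  pre <- stage("read pre", if (inherits(pre_path, "molli_series"))
    pre_path else read_series(pre_path))
  post <- stage("read post", if (inherits(post_path, "molli_series"))
    post_path else read_series(post_path))
  rp <- reg_params_from_config(config)
  sp <- pre$pixel_spacing

  if (config$moco$enabled) {
    pre_moco <- stage("MOCO pre", moco_series(
      pre, config$moco$n_iterations, rp, config$moco$tol_px))
    post_moco <- stage("MOCO post", moco_series(
      post, config$moco$n_iterations, rp, config$moco$tol_px))
  } else {
    pre_moco <- no_moco_result(pre)
    post_moco <- no_moco_result(post)
  }
  pre_fit <- pre_moco$fit
  if (config$coreg$enabled) {
    cr <- stage("co-registration", coregister_pre_post(pre_moco, post_moco, rp))
    post_fit <- cr$post_fit
  } else {
    cr <- NULL
    post_fit <- post_moco$fit
  }

  blood <- stage("blood segmentation", segment_blood(
    pre_fit, config$segmentation$threshold_ms,
    config$segmentation$min_component, config$segmentation$erosion_radius,
    post_t1 = post_fit, min_pixels = config$segmentation$min_pixels))

  ecv <- NULL; lambda <- NULL
  if (!is.null(hematocrit)) {
    hct <- parse_hematocrit(hematocrit)
    ecv <- stage("ECV", compute_ecv(pre_fit, post_fit, blood, hct))
  } else {
    warning("no hematocrit supplied: skipping ECV, writing a partition-coefficient map instead")
    lambda <- stage("partition coefficient",
                    partition_coefficient_map(pre_fit, post_fit, blood))
  }

  stage("write artifacts", {
    write_nifti(pre_fit$t1_map, file.path(out_dir, "t1_pre.nii"), c(sp, 1))
    write_nifti(post_fit$t1_map, file.path(out_dir, "t1_post.nii"), c(sp, 1))
    write_nifti(pre_fit$rss_map, file.path(out_dir, "rss_pre.nii"), c(sp, 1))
    write_nifti(post_fit$rss_map, file.path(out_dir, "rss_post.nii"), c(sp, 1))
    write_nifti(blood$mask + 0, file.path(out_dir, "blood_mask.nii"),
                c(sp, 1), datatype = "uint8")
    if (config$moco$enabled) {
      write_fields(pre_moco$fields, file.path(out_dir, "moco_fields_pre.nii"), sp)
      write_fields(if (is.null(cr)) post_moco$fields else cr$composite_fields,
                   file.path(out_dir, "moco_fields_post.nii"), sp)
    }
    if (!is.null(ecv))
      write_nifti(ifelse(is.na(ecv$ecv), -1, ecv$ecv),
                  file.path(out_dir, "ecv.nii"), c(sp, 1))
    if (!is.null(lambda))
      write_nifti(ifelse(is.na(lambda$lambda), -1, lambda$lambda),
                  file.path(out_dir, "lambda.nii"), c(sp, 1))
  })

  report <- list(
    package = "ecvmap",
    version = as.character(utils::packageVersion("ecvmap")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = list(moco = config$moco$enabled, coreg = config$coreg$enabled),
    hematocrit = if (is.null(hematocrit)) NULL else
      sig6(parse_hematocrit(hematocrit)),
    blood = list(t1_pre_ms = sig6(blood$t1_blood_pre),
                 t1_post_ms = sig6(blood$t1_blood_post),
                 n_pixels = blood$n_pixels,
                 threshold_ms = blood$threshold_used),
    delta_r1_blood_per_ms = if (!is.null(ecv)) sig6(ecv$delta_r1_blood)
      else sig6(lambda$delta_r1_blood),
    ecv = if (!is.null(ecv)) list(
      median_pct = sig6(median(ecv$ecv[ecv$valid_mask])),
      valid_pixels = sum(ecv$valid_mask)) else NULL,
    lambda = if (!is.null(lambda)) list(
      median = sig6(median(lambda$lambda[lambda$valid_mask]))) else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pre_moco = pre_moco, post_moco = post_moco, coreg = cr,
                 pre_fit = pre_fit, post_fit = post_fit, blood = blood,
                 ecv = ecv, lambda = lambda, report = report))
}

# stand-in when MOCO is disabled: identity fields, direct fit
no_moco_result <- function(series) {
  shape <- dim(series$images)[1:2]
  structure(list(corrected = series,
                 fields = replicate(n_images(series), identity_field(shape),
                                    simplify = FALSE),
                 fit = fit_map(series), original = series),
            class = "moco_result")
}
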