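#' Change in longitudinal relaxation rate
#'
#' `dR1 = 1/T1_post - 1/T1_pre`, proportional to the local concentration
#' of extracellular gadolinium contrast.
#'
#' @param t1_pre,t1_post T1 in ms (both > 0; vectors/matrices allowed).
#' @return dR1 in 1/ms.
#' @examples
#' delta_r1(1500, 300)  # 0.00266667 ms^-1
#' @export
delta_r1 <- function(t1_pre, t1_post) {
  if (any(!is.finite(t1_pre) | t1_pre <= 0) ||
      any(!is.finite(t1_post) | t1_post <= 0))
    stop("T1 values must be positive")
  1 / t1_post - 1 / t1_pre
}

#' Relaxivity model for gadolinium contrast
#'
#' `dR1 = gamma * [Gd]` with relaxivity `gamma = 4.5 L mmol^-1 s^-1` by
#' default; used by the simulator to map contrast concentration to T1
#' shortening.
#'
#' @param concentration gadolinium concentration in mmol/L (>= 0).
#' @param relaxivity relaxivity in L mmol^-1 s^-1.
#' @return dR1 in 1/s.
#' @export
gd_delta_r1 <- function(concentration, relaxivity = 4.5) {
  stopifnot(all(concentration >= 0))
  relaxivity * concentration
}

#' Normal range as mean +/- 2 SD
#'
#' @param mean,sd mean and standard deviation (sd >= 0), e.g. in ECV %.
#' @return Numeric length-2 `(low, high)`.
#' @examples
#' normal_range(25.4, 2.5)  # 20.4 30.4
#' @export
normal_range <- function(mean, sd) {
  stopifnot(sd >= 0)
  c(low = mean - 2 * sd, high = mean + 2 * sd)
}

#' Automatic blood-pool segmentation on the pre-contrast T1 map
#'
#' The pre-contrast T1 of blood (roughly 1300-1800 ms) exceeds that of most
#' tissues, so blood is segmented by thresholding the pre-contrast T1 map
#' strictly above `threshold` (default 1250 ms).  Isolated supra-threshold
#' pixels attributable to noise are removed (8-connected components smaller
#' than `min_component`), and the mask is eroded (disk of radius
#' `erosion_radius`) to drop blood-tissue boundary pixels with
#' partial-volume T1s.  Blood T1s are the medians over the final mask on
#' the pre-contrast map and (if supplied) the co-registered post-contrast
#' map.
#'
#' @param pre_t1 pre-contrast `t1_map_result`.
#' @param threshold T1 threshold in ms (strictly greater-than).
#' @param min_component minimum connected-component size kept (pixels).
#' @param erosion_radius erosion disk radius in pixels.
#' @param post_t1 optional co-registered post-contrast `t1_map_result`
#'   from which the post-contrast blood T1 median is taken.
#' @param min_pixels minimum acceptable final mask size.
#' @return A `blood_mask` object: `mask`, `t1_blood_pre`, `t1_blood_post`
#'   (NA if `post_t1` absent), `n_pixels`, `threshold_used`,
#'   `erosion_radius`.
#' @export
segment_blood <- function(pre_t1, threshold = 1250, min_component = 10,
                          erosion_radius = 1, post_t1 = NULL,
                          min_pixels = 20) {
  mask <- pre_t1$fit_ok_mask & is.finite(pre_t1$t1_map) &
    pre_t1$t1_map > threshold
  if (any(mask)) {
    labels <- .cpp_label_components(mask, 8L)
    sizes <- tabulate(labels[labels > 0])
    keep <- which(sizes >= min_component)
    mask <- matrix(labels %in% keep & labels > 0, nrow(mask), ncol(mask))
    mask <- .cpp_erode_disk(mask, erosion_radius)
  }
  if (sum(mask) < min_pixels)
    stop(sprintf(paste0(
      "blood-pool segmentation found only %d pixels above %g ms after ",
      "cleanup; supply blood T1 values manually (CLI: --blood-t1-pre/",
      "--blood-t1-post)"), sum(mask), threshold))
  t1_post <- if (!is.null(post_t1))
    median(post_t1$t1_map[mask & post_t1$fit_ok_mask], na.rm = TRUE)
  else NA_real_
  structure(
    list(mask = mask,
         t1_blood_pre = median(pre_t1$t1_map[mask], na.rm = TRUE),
         t1_blood_post = t1_post,
         n_pixels = sum(mask), threshold_used = threshold,
         erosion_radius = erosion_radius),
    class = "blood_mask")
}

#' @export
print.blood_mask <- function(x, ...) {
  cat(sprintf("blood mask: %d px (T1 > %g ms, erosion r=%g); blood T1 pre %.0f ms, post %s ms\n",
              x$n_pixels, x$threshold_used, x$erosion_radius,
              x$t1_blood_pre,
              if (is.na(x$t1_blood_post)) "NA" else
                sprintf("%.0f", x$t1_blood_post)))
  invisible(x)
}

#' Pixel-wise extracellular volume fraction map
#'
#' `ECV(%) = 100 (1 - hematocrit) * dR1_pixel / dR1_blood`, where
#' `dR1 = 1/T1_post - 1/T1_pre` and the blood term comes from the
#' segmented blood-pool medians.  Pixels where either fit failed are
#' invalid; negative raw ECV is marked invalid but the raw value is kept.
#' Displayed values are clipped to `[0, 100]`.
#'
#' @param pre_t1 pre-contrast `t1_map_result`.
#' @param post_t1_coreg co-registered post-contrast `t1_map_result`.
#' @param blood a [segment_blood()] result.  If its post-contrast median is
#'   `NA` it is computed here from `post_t1_coreg` over the mask.
#' @param hematocrit venous hematocrit, fraction in `(0, 1)`.
#' @return An `ecv_map` object: `ecv` (clipped %, NA where invalid),
#'   `ecv_raw`, `valid_mask`, `hematocrit`, `delta_r1_blood` (1/ms),
#'   `blood` and `provenance`.
#' @export
compute_ecv <- function(pre_t1, post_t1_coreg, blood, hematocrit) {
  stopifnot(hematocrit > 0, hematocrit < 1)
  if (is.na(blood$t1_blood_post))
    blood$t1_blood_post <- median(
      post_t1_coreg$t1_map[blood$mask & post_t1_coreg$fit_ok_mask],
      na.rm = TRUE)
  dr1_blood <- delta_r1(blood$t1_blood_pre, blood$t1_blood_post)
  if (!is.finite(dr1_blood) || dr1_blood <= 0)
    stop("blood dR1 is not positive; pre/post series are likely mislabeled")
  valid <- pre_t1$fit_ok_mask & post_t1_coreg$fit_ok_mask
  dr1 <- matrix(NA_real_, nrow(valid), ncol(valid))
  dr1[valid] <- 1 / post_t1_coreg$t1_map[valid] - 1 / pre_t1$t1_map[valid]
  raw <- 100 * (1 - hematocrit) * dr1 / dr1_blood
  valid <- valid & is.finite(raw) & raw >= 0
  ecv <- pmin(pmax(raw, 0), 100)
  ecv[!valid] <- NA_real_
  structure(
    list(ecv = ecv, ecv_raw = raw, valid_mask = valid,
         hematocrit = hematocrit, delta_r1_blood = dr1_blood,
         blood = blood,
         provenance = list(package = "ecvmap",
                           version = as.character(utils::packageVersion("ecvmap")))),
    class = "ecv_map")
}

#' @export
print.ecv_map <- function(x, ...) {
  v <- x$ecv[x$valid_mask]
  cat(sprintf("ECV map: %d valid px; median %.1f%% (IQR %.1f-%.1f); hct %.2f, blood dR1 %.5g /ms\n",
              sum(x$valid_mask), median(v), stats::quantile(v, 0.25),
              stats::quantile(v, 0.75), x$hematocrit, x$delta_r1_blood))
  invisible(x)
}

#' Hematocrit-free partition-coefficient map
#'
#' `lambda = dR1_pixel / dR1_blood`; the ECV map equals
#' `(1 - hematocrit) * lambda * 100`, so lambda can be mapped when no
#' hematocrit is available (at the cost of inter-subject variability).
#'
#' @inheritParams compute_ecv
#' @return A list: `lambda` (matrix, unitless), `valid_mask`,
#'   `delta_r1_blood`, `blood`.
#' @export
partition_coefficient_map <- function(pre_t1, post_t1_coreg, blood) {
  if (is.na(blood$t1_blood_post))
    blood$t1_blood_post <- median(
      post_t1_coreg$t1_map[blood$mask & post_t1_coreg$fit_ok_mask],
      na.rm = TRUE)
  dr1_blood <- delta_r1(blood$t1_blood_pre, blood$t1_blood_post)
  if (!is.finite(dr1_blood) || dr1_blood <= 0)
    stop("blood dR1 is not positive; pre/post series are likely mislabeled")
  valid <- pre_t1$fit_ok_mask & post_t1_coreg$fit_ok_mask
  lam <- matrix(NA_real_, nrow(valid), ncol(valid))
  lam[valid] <- (1 / post_t1_coreg$t1_map[valid] -
                 1 / pre_t1$t1_map[valid]) / dr1_blood
  list(lambda = lam, valid_mask = valid, delta_r1_blood = dr1_blood,
       blood = blood)
}
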