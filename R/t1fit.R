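#' @title Pixel-wise MOLLI T1 fitting
#' @description Three-parameter magnitude inversion-recovery fitting
#'   `s(TI) = |A - B exp(-TI/T1*)|` by multi-start downhill simplex, with
#'   Look-Locker correction `T1 = T1* (B/A - 1)` and a sum-of-squares
#'   residual (goodness-of-fit) map.
#' @name t1fit
NULL

# default multi-start T1* seeds (ms); the magnitude model is multimodal
# near signal nulls, so a single start is not reliable
T1_STARTS_DEFAULT <- c(150, 400, 800, 1500)

# physiological/protocol acceptance bounds for a fitted pixel
FIT_BOUNDS <- list(t1_min = 1, t1_max = 5000, ba_min = 1, ba_max = 3)

t1_map_result <- function(a_map, b_map, t1_star_map, t1_map, rss_map,
                          fit_ok_mask, meta = list()) {
  structure(list(a_map = a_map, b_map = b_map, t1_star_map = t1_star_map,
                 t1_map = t1_map, rss_map = rss_map,
                 fit_ok_mask = fit_ok_mask, meta = meta),
            class = "t1_map_result")
}

#' @export
print.t1_map_result <- function(x, ...) {
  ok <- x$fit_ok_mask
  cat(sprintf("T1 map %dx%d px: %d/%d pixels fit ok",
              nrow(x$t1_map), ncol(x$t1_map), sum(ok), length(ok)))
  if (any(ok))
    cat(sprintf("; T1 median %.0f ms (IQR %.0f-%.0f)",
                median(x$t1_map[ok]),
                stats::quantile(x$t1_map[ok], 0.25),
                stats::quantile(x$t1_map[ok], 0.75)))
  cat("\n")
  invisible(x)
}

#' Look-Locker correction
#'
#' Converts the apparent recovery constant T1* of a MOLLI fit to the true
#' T1 via `T1 = T1* (B/A - 1)`.
#'
#' @param A,B fitted model parameters (A > 0).
#' @param t1_star apparent T1* in ms.
#' @return Corrected T1 in ms (`NA` where A <= 0).
#' @examples
#' look_locker_correct(1, 2, 600)  # 600: B = 2A leaves T1 = T1*
#' @export
look_locker_correct <- function(A, B, t1_star) {
  out <- t1_star * (B / A - 1)
  out[!is.finite(A) | A <= 0] <- NA_real_
  out
}

#' Fit a single pixel's inversion-recovery curve
#'
#' Minimizes `sum_i (s_i - |A - B exp(-TI_i/T1*)|)^2` by downhill simplex
#' from multiple T1* starting points, keeping the lowest residual.
#'
#' @param signal numeric vector of magnitudes (>= 4 samples).
#' @param ti_values inversion times in ms, same length, distinct.
#' @param t1_starts T1* starting values for the multi-start search.
#' @return A list `(A, B, t1_star, t1, rss, fit_ok)`; `fit_ok` is `FALSE`
#'   for non-finite/all-zero input or parameters outside the acceptance
#'   bounds (1 <= T1 <= 5000 ms, 1 <= B/A <= 3).
#' @export
fit_pixel <- function(signal, ti_values, t1_starts = T1_STARTS_DEFAULT) {
  if (length(signal) < 4L) stop("need at least 4 samples per pixel")
  if (length(signal) != length(ti_values))
    stop("signal and ti_values must have the same length")
  if (anyDuplicated(ti_values)) stop("inversion times must be distinct")
  fit <- .cpp_fit_molli(matrix(signal, nrow = 1), as.numeric(ti_values),
                        t1_starts, 500L, 1L)
  pixel_result(fit[1, 1], fit[1, 2], fit[1, 3], fit[1, 4])
}

pixel_result <- function(A, B, t1_star, rss) {
  t1 <- look_locker_correct(A, B, t1_star)
  ok <- is.finite(A) && is.finite(t1) && A > 0 &&
    t1 >= FIT_BOUNDS$t1_min && t1 <= FIT_BOUNDS$t1_max &&
    B / A >= FIT_BOUNDS$ba_min && B / A <= FIT_BOUNDS$ba_max
  list(A = A, B = B, t1_star = t1_star,
       t1 = if (is.finite(t1)) t1 else NA_real_,
       rss = rss, fit_ok = ok)
}

#' Pixel-wise T1 map from a MOLLI series
#'
#' Applies [fit_pixel()] at every pixel and assembles parameter maps, the
#' Look-Locker-corrected T1 map, the residual sum-of-squares map used as a
#' goodness-of-fit map, and the per-pixel acceptance mask.  Pixels whose
#' fit fails are flagged, never fatal.
#'
#' @param series a [molli_series()].
#' @param t1_starts multi-start T1* seeds (ms).
#' @return A `t1_map_result`.
#' @export
fit_map <- function(series, t1_starts = T1_STARTS_DEFAULT) {
  d <- dim(series$images)
  npix <- d[1] * d[2]
  sig <- matrix(series$images, npix, d[3])
  # pixels with essentially no signal relative to the series peak (air,
  # or interpolation residue after warping an empty region) are not fit
  rowmax <- Reduce(pmax, lapply(seq_len(d[3]), function(j) sig[, j]))
  empty <- !is.finite(rowmax) | rowmax < 1e-6 * max(rowmax, na.rm = TRUE)
  sig[empty, ] <- NA_real_
  fit <- .cpp_fit_molli(sig, series$ti_values, t1_starts, 500L, 1L)
  a <- matrix(fit[, 1], d[1], d[2])
  b <- matrix(fit[, 2], d[1], d[2])
  t1s <- matrix(fit[, 3], d[1], d[2])
  rss <- matrix(fit[, 4], d[1], d[2])
  t1 <- matrix(look_locker_correct(fit[, 1], fit[, 2], fit[, 3]), d[1], d[2])
  ok <- is.finite(a) & is.finite(t1) & a > 0 &
    t1 >= FIT_BOUNDS$t1_min & t1 <= FIT_BOUNDS$t1_max &
    b / a >= FIT_BOUNDS$ba_min & b / a <= FIT_BOUNDS$ba_max
  ok[is.na(ok)] <- FALSE
  t1_map_result(a, b, t1s, t1, rss, ok,
                meta = list(ti_values = series$ti_values,
                            contrast_phase = series$contrast_phase,
                            method = "simplex"))
}

#' Synthesize a motion-free image at a given inversion time
#'
#' Evaluates `|A - B exp(-ti/T1*)|` per pixel from fitted (or initial)
#' parameters.  On pixels flagged not-ok the fully recovered value `A` is
#' returned, so synthetic images stay usable as registration targets.
#'
#' @param result a `t1_map_result`.
#' @param ti inversion time in ms.
#' @return A matrix image.
#' @export
synthesize_image <- function(result, ti) {
  img <- abs(result$a_map - result$b_map * exp(-ti / result$t1_star_map))
  bad <- !result$fit_ok_mask | !is.finite(img)
  img[bad] <- result$a_map[bad]
  img[!is.finite(img)] <- 0
  img
}

#' Crude two-point initial T1 estimate
#'
#' Closed-form per-pixel estimate from only the shortest- and longest-TI
#' images, assuming full recovery at the longest TI (`A = s(TI_max)`) and
#' ideal inversion (`B = 2A`).  When `s(TI_min) < s(TI_max)` the short-TI
#' sample is taken to be still inverted (`s = B exp(-TI/T1) - A`), which
#' holds for all tissue T1s of interest at TI_min ~ 110 ms; otherwise the
#' non-inverted branch is used.  Degenerate pixels fall back to 1000 ms.
#' The estimate is crude but sufficient to seed motion correction.
#'
#' @param series a [molli_series()] with >= 2 images.
#' @param t1_default fallback T1 (ms) for degenerate pixels.
#' @return A `t1_map_result` with `meta$method = "two-point"`.
#' @export
initial_t1_estimate <- function(series, t1_default = 1000) {
  if (n_images(series) < 2L) stop("need at least 2 images")
  i_min <- which.min(series$ti_values)
  i_max <- which.max(series$ti_values)
  ti_min <- series$ti_values[i_min]
  s_min <- series_image(series, i_min)
  s_max <- series_image(series, i_max)
  a <- s_max
  ok <- is.finite(a) & a > 0
  t1 <- matrix(t1_default, nrow(a), ncol(a))
  # inverted branch: s_min = 2A exp(-ti/T1) - A  =>  T1 = ti / log(2A/(s_min+A))
  ratio_inv <- 2 * a / (s_min + a)
  use_inv <- ok & (s_min < s_max) & is.finite(ratio_inv) & ratio_inv > 1
  t1[use_inv] <- ti_min / log(ratio_inv[use_inv])
  # non-inverted branch: s_min = A - 2A exp(-ti/T1)
  ratio_non <- 2 * a / (a - s_min)
  use_non <- ok & !use_inv & is.finite(ratio_non) & ratio_non > 1 & s_min < a
  t1[use_non] <- ti_min / log(ratio_non[use_non])
  t1[!is.finite(t1) | t1 <= 0 | t1 > 5000] <- t1_default
  rss <- matrix(0, nrow(a), ncol(a))
  t1_map_result(a, 2 * a, t1, t1, rss, ok,
                meta = list(method = "two-point", crude = TRUE))
}
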