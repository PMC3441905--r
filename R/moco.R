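#' Registration parameters
#'
#' Controls the variational optical-flow (demons-style) non-rigid
#' registration: per-iteration displacement updates from intensity
#' differences and gradients, Gaussian ("fluid") smoothing of each update
#' and Gaussian ("diffusion") regularization of the accumulated field,
#' within a coarse-to-fine multi-resolution pyramid.
#'
#' @param sigma_field Gaussian sigma (px) regularizing the accumulated
#'   field each iteration.
#' @param sigma_fluid Gaussian sigma (px) smoothing each raw update.
#' @param n_levels pyramid levels (downsampling by 2 per level).
#' @param max_iter maximum iterations per level.
#' @param tol stop a level once the mean update magnitude (px) falls below.
#' @param step_cap maximum per-iteration displacement update (px).
#' @return A named list of parameters.
#' @export
reg_params <- function(sigma_field = 4, sigma_fluid = 1, n_levels = 3,
                       max_iter = 50, tol = 0.01, step_cap = 1) {
  list(sigma_field = sigma_field, sigma_fluid = sigma_fluid,
       n_levels = n_levels, max_iter = max_iter, tol = tol,
       step_cap = step_cap)
}

downsample2 <- function(img) {
  s <- .cpp_gauss_smooth(img, 1)
  s[seq(1, nrow(img), by = 2), seq(1, ncol(img), by = 2), drop = FALSE]
}

norm_image <- function(img) {
  sc <- stats::quantile(img, 0.99, names = FALSE)
  if (sc <= 0) sc <- max(img)
  if (sc <= 0) return(img)
  img / sc
}

demons_level <- function(moving, fixed, dy, dx, params) {
  .cpp_demons_level(moving, fixed, dy, dx, params$sigma_field,
                    params$sigma_fluid, as.integer(params$max_iter),
                    params$tol, params$step_cap)
}

#' Non-rigid registration of two images
#'
#' Estimates a smooth dense displacement field such that
#' `warp(moving, field)` matches `fixed`, by a classical optical-flow
#' (demons) scheme with Gaussian regularization inside a multi-resolution
#' pyramid.  Intensities are pre-normalized per image.
#'
#' @param moving,fixed numeric matrices of the same shape.
#' @param params a [reg_params()] list.
#' @param init optional [deformation_field()] warm start (e.g. the field
#'   from a previous outer iteration); the registration refines it and
#'   may undo parts of it, so re-registering with a warm start replaces
#'   rather than compounds earlier estimates.
#' @return A [deformation_field()] (pull semantics, pixels).  Degenerate
#'   (near-constant) image pairs return an identity field with a warning.
#' @export
register_nonrigid <- function(moving, fixed, params = reg_params(),
                              init = NULL) {
  if (!all(dim(moving) == dim(fixed))) stop("images must share a shape")
  if (any(!is.finite(moving)) || any(!is.finite(fixed)))
    stop("image intensities must be finite")
  if (stats::sd(moving) < 1e-10 || stats::sd(fixed) < 1e-10) {
    warning("degenerate (constant) image; returning identity field")
    return(identity_field(dim(fixed)))
  }
  mov <- norm_image(moving)
  fix <- norm_image(fixed)
  # no mutual structure at all (e.g. pure noise): deforming would be a
  # random walk, so return identity and flag it
  cc0 <- suppressWarnings(stats::cor(as.vector(mov), as.vector(fix)))
  if (!is.finite(cc0) || cc0 < 0.1) {
    warning("images share no mutual structure; returning identity field flagged low-confidence")
    out <- identity_field(dim(fixed))
    out$low_confidence <- TRUE
    return(out)
  }
  # build pyramid, coarsest first
  movs <- list(mov); fixs <- list(fix)
  for (l in seq_len(params$n_levels - 1)) {
    if (min(dim(movs[[1]])) < 16) break
    movs <- c(list(downsample2(movs[[1]])), movs)
    fixs <- c(list(downsample2(fixs[[1]])), fixs)
  }
  scale <- 2^(length(movs) - 1)
  if (is.null(init)) {
    dy <- matrix(0, nrow(movs[[1]]), ncol(movs[[1]]))
    dx <- dy
  } else {
    dy <- .cpp_resize_bilinear(init$dy, nrow(movs[[1]]), ncol(movs[[1]])) / scale
    dx <- .cpp_resize_bilinear(init$dx, nrow(movs[[1]]), ncol(movs[[1]])) / scale
  }
  for (l in seq_along(movs)) {
    if (l > 1) {
      dy <- .cpp_resize_bilinear(dy, nrow(movs[[l]]), ncol(movs[[l]])) * 2
      dx <- .cpp_resize_bilinear(dx, nrow(movs[[l]]), ncol(movs[[l]])) * 2
    }
    res <- demons_level(movs[[l]], fixs[[l]], dy, dx, params)
    dy <- res$dy; dx <- res$dx
  }
  out <- deformation_field(dy, dx, provenance = "moco")
  # flag registrations without usable structure (e.g. pure noise): the
  # aligned images should correlate if the field means anything
  cc <- suppressWarnings(stats::cor(as.vector(.cpp_warp(mov, dy, dx, 1L)),
                                    as.vector(fix)))
  out$low_confidence <- !is.finite(cc) || cc < 0.3
  if (out$low_confidence)
    warning("registration found little mutual structure; field flagged low-confidence")
  out
}

#' Iterative motion correction of a MOLLI series
#'
#' Corrects respiratory motion by registering each measured image to a
#' motion-free synthetic image of matching inversion-recovery contrast.
#' The reference respiratory position is that of the longest-TI image
#' (highest SNR, nearly fully recovered).  Iteration 0 registers the
#' shortest-TI image to the longest-TI image (these avoid tissue nulling)
#' and seeds a crude two-point T1 estimate; each subsequent iteration
#' synthesizes one image per acquired TI from the current fit, registers
#' every measured image to its synthetic counterpart, composes the update
#' with the accumulated field, and refits.  The final corrected images are
#' each produced by warping the ORIGINAL image exactly once with the
#' accumulated field (5th-order interpolation), so no pixel is resampled
#' twice.
#'
#' @param series a [molli_series()].
#' @param n_iterations outer MOCO iterations (default 2).
#' @param params registration parameters ([reg_params()]).
#' @param tol stop early once the largest per-image displacement update
#'   falls below this many pixels (default 0.5).
#' @param sigma_field_schedule per-outer-iteration field regularization
#'   sigma (px); the first iteration faces synthetics built from the
#'   crude two-point seed, so it only trusts coarse-scale motion
#'   (stronger smoothing), while later iterations refine at the base
#'   sigma.  Recycled for extra iterations.
#' @param verbose emit per-iteration progress messages.
#' @return A `moco_result`: `corrected` (a [molli_series()]), `fields`
#'   (list of accumulated [deformation_field()]s, one per image), `fit`
#'   (final [fit_map()] result on the corrected series), and `original`.
#' @export
moco_series <- function(series, n_iterations = 2, params = reg_params(),
                        tol = 0.5,
                        sigma_field_schedule = c(2 * params$sigma_field,
                                                 params$sigma_field),
                        verbose = FALSE) {
  n <- n_images(series)
  shape <- dim(series$images)[1:2]
  i_max <- longest_ti_index(series)
  i_min <- which.min(series$ti_values)
  fields <- replicate(n, identity_field(shape), simplify = FALSE)
  iter_params <- function(iter) {
    p <- params
    p$sigma_field <- sigma_field_schedule[min(max(iter, 1),
                                              length(sigma_field_schedule))]
    p
  }

  # iteration 0: align the shortest-TI image with the longest-TI anchor,
  # then a crude two-point T1 estimate at the anchor position
  fields[[i_min]] <- try_register(series_image(series, i_min),
                                  series_image(series, i_max),
                                  fields[[i_min]], iter_params(1), i_min,
                                  verbose)
  two <- molli_series(
    array(c(warp(series_image(series, i_min), fields[[i_min]], 5L),
            series_image(series, i_max)), dim = c(shape, 2L)),
    series$ti_values[c(i_min, i_max)], series$pixel_spacing,
    series$contrast_phase)
  result <- initial_t1_estimate(two)

  for (iter in seq_len(n_iterations)) {
    max_update <- 0
    for (i in seq_len(n)) {
      # re-register the ORIGINAL image to the current synthetic, warm-
      # started from the accumulated field: the field is replaced, not
      # compounded, so errors from earlier (cruder) synthetics can be
      # undone once the fit improves
      synth <- synthesize_image(result, series$ti_values[i])
      new_field <- try_register(series_image(series, i), synth, NULL,
                                iter_params(iter), i, verbose,
                                init = fields[[i]])
      if (is.null(new_field)) next
      max_update <- max(max_update,
                        max(abs(new_field$dy - fields[[i]]$dy),
                            abs(new_field$dx - fields[[i]]$dx)))
      fields[[i]] <- new_field
    }
    corrected <- warp_series(series, fields)
    result <- fit_map(corrected)
    if (verbose)
      message(sprintf("MOCO iteration %d: max displacement update %.2f px",
                      iter, max_update))
    if (max_update < tol) break
  }
  corrected <- warp_series(series, fields)
  result <- fit_map(corrected)
  structure(list(corrected = corrected, fields = fields, fit = result,
                 original = series),
            class = "moco_result")
}

# single-warp helper: each output image interpolated once from the original
warp_series <- function(series, fields, interpolation_order = 5L) {
  imgs <- series$images
  out <- imgs
  for (i in seq_len(dim(imgs)[3])) {
    w <- warp(imgs[, , i], fields[[i]], interpolation_order)
    w[w < 0] <- 0
    out[, , i] <- w
  }
  molli_series(out, series$ti_values, series$pixel_spacing,
               series$contrast_phase, series$meta)
}

try_register <- function(moving, fixed, fallback, params, index, verbose,
                         init = NULL) {
  res <- tryCatch(register_nonrigid(moving, fixed, params, init = init),
                  error = function(e) {
                    message(sprintf(
                      "registration failed for image %d (%s); keeping previous field",
                      index, conditionMessage(e)))
                    NULL
                  })
  if (is.null(res)) fallback else res
}
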