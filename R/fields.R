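#' Dense 2-D deformation field
#'
#' A per-pixel displacement map in pixel units with pull (backward-warp)
#' semantics: `warp(img, field)` samples the input image at
#' `x + displacement(x)` for every output pixel `x`.
#'
#' @param dy,dx numeric matrices of row/column displacements (pixels).
#' @param provenance one of `"identity"`, `"moco"`, `"coreg"`,
#'   `"composite"`, `"simulated"`.
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(dy, dx, provenance = "moco") {
  if (!all(dim(dy) == dim(dx)))
    stop("dy and dx must have the same shape")
  if (any(!is.finite(dy)) || any(!is.finite(dx)))
    stop("displacement field must be finite everywhere")
  structure(list(dy = dy, dx = dx, reference_shape = dim(dy),
                 provenance = provenance),
            class = "deformation_field")
}

#' Identity deformation field
#' @param shape (rows, cols) in pixels.
#' @return A zero-displacement `deformation_field`.
#' @export
identity_field <- function(shape) {
  z <- matrix(0, shape[1], shape[2])
  deformation_field(z, z, provenance = "identity")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dy^2 + x$dx^2)
  cat(sprintf("deformation field %dx%d px (%s): mean |d| = %.3f, max = %.3f px\n",
              x$reference_shape[1], x$reference_shape[2], x$provenance,
              mean(mag), max(mag)))
  invisible(x)
}

#' Warp an image by a deformation field
#'
#' Samples the image at `x + displacement(x)` using B-spline interpolation.
#' The default 5th-order interpolator minimizes loss of spatial resolution;
#' order 1 (bilinear) is used internally during registration iterations.
#' Sample positions outside the image take nearest-edge values.
#'
#' @param image numeric matrix.
#' @param field a [deformation_field()] of the same shape.
#' @param interpolation_order 0 (nearest), 1 (bilinear), 3 or 5 (B-spline).
#' @return The warped image (matrix).
#' @export
warp <- function(image, field, interpolation_order = 5L) {
  if (!all(dim(image) == field$reference_shape))
    stop("image and field shapes must match")
  if (!interpolation_order %in% c(0L, 1L, 3L, 5L))
    stop("interpolation_order must be one of 0, 1, 3, 5")
  .cpp_warp(image, field$dy, field$dx, as.integer(interpolation_order))
}

#' Compose two deformation fields
#'
#' Returns the field `c` with `c(x) = first(x + second(x)) + second(x)`,
#' i.e. `warp(img, c)` is equivalent (up to interpolation tolerance) to
#' `warp(warp(img, first), second)`.  Composing fields and warping the
#' original image once avoids the resolution loss of repeated resampling.
#'
#' @param first,second [deformation_field()]s with the same reference shape.
#' @param provenance provenance tag of the result.
#' @return The composite `deformation_field`.
#' @export
compose_fields <- function(first, second, provenance = "composite") {
  if (!all(first$reference_shape == second$reference_shape))
    stop("fields must share a reference shape")
  # resample `first` at x + second(x) with bilinear interpolation
  dy1 <- .cpp_warp(first$dy, second$dy, second$dx, 1L)
  dx1 <- .cpp_warp(first$dx, second$dy, second$dx, 1L)
  deformation_field(dy1 + second$dy, dx1 + second$dx, provenance)
}

# numerical inverse by fixed-point iteration: find g with
# f(x + g(x)) + g(x) = 0
invert_field <- function(field, n_iter = 30L, tol = 1e-3) {
  gy <- -field$dy; gx <- -field$dx
  for (k in seq_len(n_iter)) {
    fy <- .cpp_warp(field$dy, gy, gx, 1L)
    fx <- .cpp_warp(field$dx, gy, gx, 1L)
    ny <- -fy; nx <- -fx
    delta <- max(abs(ny - gy), abs(nx - gx))
    gy <- ny; gx <- nx
    if (delta < tol) break
  }
  deformation_field(gy, gx, provenance = "composite")
}

field_magnitude <- function(field) sqrt(field$dy^2 + field$dx^2)
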