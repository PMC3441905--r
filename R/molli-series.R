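#' MOLLI image series
#'
#' Container for a MOLLI inversion-recovery series: a stack of 2-D magnitude
#' images, one per inversion time, in acquisition order.
#'
#' @param images numeric array `[rows, cols, n]` of magnitude images
#'   (non-negative), or a list of matrices of identical shape.
#' @param ti_values numeric vector of inversion times in ms, one per image,
#'   aligned with the third dimension of `images`.
#' @param pixel_spacing numeric length-2, in-plane pixel spacing in mm
#'   (row, column).
#' @param contrast_phase `"pre"` or `"post"` contrast.
#' @param meta named list of free-form acquisition tags.
#'
#' @return An object of class `molli_series` with elements `images`,
#'   `ti_values`, `pixel_spacing`, `contrast_phase`, `meta`.
#' @export
molli_series <- function(images, ti_values, pixel_spacing = c(2.1, 1.9),
                         contrast_phase = c("pre", "post"), meta = list()) {
  if (is.list(images)) {
    shp <- dim(images[[1]])
    images <- array(unlist(images, use.names = FALSE),
                    dim = c(shp, length(images)))
  }
  if (length(dim(images)) != 3L)
    stop("`images` must be a [rows, cols, n] array or list of matrices")
  ti_values <- as.numeric(ti_values)
  n <- dim(images)[3L]
  if (length(ti_values) != n)
    stop(sprintf("series has %d images but %d inversion times; one TI per image is required",
                 n, length(ti_values)))
  if (anyDuplicated(ti_values))
    stop("inversion times must be distinct")
  if (any(!is.finite(ti_values)) || any(ti_values <= 0))
    stop("inversion times must be finite and > 0")
  contrast_phase <- match.arg(contrast_phase)
  structure(
    list(images = images, ti_values = ti_values,
         pixel_spacing = as.numeric(pixel_spacing),
         contrast_phase = contrast_phase, meta = meta),
    class = "molli_series")
}

#' @export
print.molli_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("MOLLI series (%s-contrast): %d images of %dx%d px\n",
              x$contrast_phase, d[3], d[1], d[2]))
  cat("  TI (ms):", paste(round(x$ti_values, 1), collapse = ", "), "\n")
  invisible(x)
}

n_images <- function(series) dim(series$images)[3L]

series_image <- function(series, i) series$images[, , i]

# index of the image with the globally longest inversion time
longest_ti_index <- function(series) which.max(series$ti_values)

#' @export
`[.molli_series` <- function(x, i) {
  molli_series(x$images[, , i, drop = FALSE], x$ti_values[i],
               x$pixel_spacing, x$contrast_phase, x$meta)
}
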