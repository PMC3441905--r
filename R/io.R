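#' Write a MOLLI series as NIfTI plus a JSON sidecar
#'
#' The image stack goes to one 3-D `.nii` (slices in acquisition order);
#' the inversion times and acquisition tags go to a JSON sidecar with the
#' same basename.
#'
#' @param series a [molli_series()].
#' @param path output `.nii` path.
#' @param slice_thickness slice thickness in mm stored in the header.
#' @return The sidecar path, invisibly.
#' @export
write_series <- function(series, path, slice_thickness = 6) {
  write_nifti(series$images, path,
              pixdim = c(series$pixel_spacing, slice_thickness))
  sidecar <- sidecar_path(path)
  jsonlite::write_json(
    list(ti_ms = series$ti_values,
         contrast_phase = series$contrast_phase,
         pixel_spacing_mm = series$pixel_spacing,
         meta = series$meta),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

sidecar_path <- function(path) sub("\\.nii$", ".json", path)

#' Read a MOLLI series from NIfTI + TI sidecar
#'
#' @param path a `.nii` file (one 2-D image per slice, acquisition order).
#' @param ti_source the JSON sidecar carrying `ti_ms` (and optionally
#'   `contrast_phase`, `pixel_spacing_mm`, `meta`); defaults to the file
#'   with the same basename and `.json` extension.  A bare numeric vector
#'   of TIs (ms) is also accepted.
#' @return A [molli_series()].
#' @export
read_series <- function(path, ti_source = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nii <- read_nifti(path)
  n <- dim(nii$data)[3]
  if (is.numeric(ti_source)) {
    side <- list(ti_ms = ti_source)
  } else {
    sc <- if (is.null(ti_source)) sidecar_path(path) else ti_source
    if (!file.exists(sc))
      stop("no TI sidecar found at ", sc,
           "; supply `ti_source` (JSON with field `ti_ms`, or a numeric vector)")
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(side$ti_ms)) stop("sidecar ", sc, " lacks field `ti_ms`")
  }
  ti <- as.numeric(side$ti_ms)
  if (length(ti) != n)
    stop(sprintf("series %s has %d images but %d inversion times in sidecar",
                 path, n, length(ti)))
  molli_series(nii$data, ti,
               pixel_spacing = if (!is.null(side$pixel_spacing_mm))
                 as.numeric(side$pixel_spacing_mm) else nii$pixdim[1:2],
               contrast_phase = if (!is.null(side$contrast_phase))
                 side$contrast_phase else "pre",
               meta = if (!is.null(side$meta)) as.list(side$meta) else list())
}

# fields as one 3-D NIfTI: slices alternate (dy_1, dx_1, dy_2, dx_2, ...)
write_fields <- function(fields, path, pixel_spacing = c(1, 1)) {
  shape <- fields[[1]]$reference_shape
  arr <- array(0, dim = c(shape, 2L * length(fields)))
  for (i in seq_along(fields)) {
    arr[, , 2L * i - 1L] <- fields[[i]]$dy
    arr[, , 2L * i] <- fields[[i]]$dx
  }
  write_nifti(arr, path, pixdim = c(pixel_spacing, 1),
              descrip = "deformation dy/dx px")
  invisible(path)
}

#' Parse a hematocrit given as fraction or percent
#'
#' Accepts `0.42`, `"0.42"`, `42`, or `"42%"`; anything above 1 is treated
#' as a percentage.
#' @param x scalar value or string.
#' @return Hematocrit as a fraction in (0, 1).
#' @export
parse_hematocrit <- function(x) {
  if (is.character(x))
    x <- suppressWarnings(as.numeric(sub("%$", "", trimws(x))))
  if (!is.finite(x)) stop("cannot parse hematocrit")
  if (x > 1) x <- x / 100
  if (x <= 0 || x >= 1) stop("hematocrit must lie in (0, 1)")
  x
}
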