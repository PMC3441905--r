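#' Digital short-axis cardiac phantom
#'
#' Describes a simple short-axis-like section: a circular blood pool inside
#' a myocardial ring on a low-signal background, with assigned pre- and
#' post-contrast T1 values.  The post-contrast myocardial T1 is derived from
#' the requested myocardial ECV, the hematocrit and the blood T1s so that
#' the simulated ground truth is exactly consistent with the ECV model.
#'
#' Defaults follow a typical 1.5 T protocol: acquisition matrix 192 x 130,
#' in-plane voxel 2.1 x 1.9 mm, blood T1 1500 ms pre / 300 ms post,
#' myocardium 1000 ms pre, ECV 25%, hematocrit 0.42.
#'
#' @param grid_shape image matrix size (rows, cols) in pixels.
#' @param blood_center blood-pool centre (row, col); default image centre.
#' @param blood_radius radius of the blood pool in pixels.
#' @param myo_inner_radius,myo_outer_radius inner/outer radii of the
#'   myocardial ring in pixels.
#' @param t1_blood_pre,t1_myo_pre,t1_blood_post native/post-contrast T1 (ms).
#' @param ecv_myo myocardial extracellular volume fraction in `[0, 1)`.
#' @param hematocrit venous hematocrit as a fraction in `(0, 1)`.
#' @param background_t1 T1 (ms) assigned to background pixels.
#' @param proton_density named proton densities (arbitrary units) for
#'   `blood`, `myocardium` and `background`.
#' @param shading_amplitude relative amplitude of the smooth deterministic
#'   intensity shading (coil-profile surrogate) applied to proton density.
#' @param pixel_spacing in-plane pixel spacing (mm).
#'
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(192L, 130L),
                         blood_center = NULL,
                         blood_radius = 14,
                         myo_inner_radius = 17,
                         myo_outer_radius = 23,
                         t1_blood_pre = 1500,
                         t1_myo_pre = 1000,
                         t1_blood_post = 300,
                         ecv_myo = 0.25,
                         hematocrit = 0.42,
                         background_t1 = 250,
                         proton_density = c(blood = 1.1, myocardium = 0.9,
                                            background = 0.05),
                         shading_amplitude = 0.1,
                         pixel_spacing = c(2.1, 1.9)) {
  if (is.null(blood_center)) blood_center <- (grid_shape + 1) / 2
  stopifnot(blood_radius < myo_inner_radius,
            myo_inner_radius < myo_outer_radius,
            t1_blood_pre > 0, t1_myo_pre > 0, t1_blood_post > 0,
            background_t1 > 0,
            ecv_myo >= 0, ecv_myo < 1,
            hematocrit > 0, hematocrit < 1)
  if (t1_blood_post >= t1_blood_pre)
    stop("post-contrast blood T1 must be shorter than pre-contrast blood T1")
  structure(
    list(grid_shape = as.integer(grid_shape), blood_center = blood_center,
         blood_radius = blood_radius, myo_inner_radius = myo_inner_radius,
         myo_outer_radius = myo_outer_radius, t1_blood_pre = t1_blood_pre,
         t1_myo_pre = t1_myo_pre, t1_blood_post = t1_blood_post,
         ecv_myo = ecv_myo, hematocrit = hematocrit,
         background_t1 = background_t1, proton_density = proton_density,
         shading_amplitude = shading_amplitude,
         pixel_spacing = pixel_spacing),
    class = "phantom_spec")
}

#' MOLLI inversion-time schedule
#'
#' Builds the acquired-order TI list for the 8-image, 11-heartbeat MOLLI
#' protocols with two inversions.  The "3-5" variant acquires 3 images after
#' the first inversion and 5 after the second; "5-3" acquires 5 then 3.
#' Within an inversion block, successive TIs are separated by one RR
#' interval (`60000 / heart_rate` ms); the second inversion starts at
#' `ti_min + ti_increment`.
#'
#' @param protocol_variant `"3-5"` or `"5-3"`.
#' @param heart_rate heart rate in beats per minute.
#' @param ti_min minimum inversion time (ms); default 110.
#' @param ti_increment inversion-time increment between the two inversion
#'   blocks (ms); default 80.
#'
#' @return A `ti_schedule` object: `ti_values` (ms, acquisition order),
#'   `protocol_variant`, `heart_rate`, `ti_min`, `ti_increment`.
#' @examples
#' build_ti_schedule("5-3", heart_rate = 60)$ti_values
#' @export
build_ti_schedule <- function(protocol_variant = c("5-3", "3-5"),
                              heart_rate = 60, ti_min = 110,
                              ti_increment = 80) {
  protocol_variant <- match.arg(protocol_variant)
  stopifnot(heart_rate > 0, ti_min > 0, ti_increment > 0)
  rr <- 60000 / heart_rate
  n1 <- if (protocol_variant == "5-3") 5L else 3L
  n2 <- 8L - n1
  ti <- c(ti_min + (seq_len(n1) - 1) * rr,
          ti_min + ti_increment + (seq_len(n2) - 1) * rr)
  structure(
    list(ti_values = ti, protocol_variant = protocol_variant,
         heart_rate = heart_rate, ti_min = ti_min,
         ti_increment = ti_increment),
    class = "ti_schedule")
}

#' Respiratory motion specification for the simulator
#'
#' Zero amplitudes yield identity motion.  If `per_image_translation` is
#' given it is used verbatim; otherwise a smooth random drift curve with
#' maximum excursion `drift_amplitude` is drawn (seeded).  An optional
#' smooth non-rigid component adds Gaussian-filtered random displacements.
#'
#' @param per_image_translation optional `n x 2` matrix of (dy, dx)
#'   translations in pixels, one row per image.
#' @param drift_amplitude maximum |translation| of the drift curve (px).
#' @param nonrigid_amplitude maximum |displacement| of the non-rigid
#'   component (px).
#' @param nonrigid_smoothness Gaussian kernel scale of the non-rigid
#'   component (px).
#' @param seed integer seed making the drawn motion reproducible.
#' @return A `motion_spec` object.
#' @export
motion_spec <- function(per_image_translation = NULL, drift_amplitude = 0,
                        nonrigid_amplitude = 0, nonrigid_smoothness = 12,
                        seed = 1L) {
  structure(
    list(per_image_translation = per_image_translation,
         drift_amplitude = drift_amplitude,
         nonrigid_amplitude = nonrigid_amplitude,
         nonrigid_smoothness = nonrigid_smoothness, seed = seed),
    class = "motion_spec")
}

#' Post-contrast myocardial T1 consistent with a target ECV
#'
#' Inverts the ECV relation: given the target ECV, hematocrit and the pre-
#' and post-contrast blood T1s, returns the post-contrast myocardial T1 for
#' which the ECV computation reproduces the target exactly
#' (`dR1_myo = ecv / (1 - hct) * dR1_blood`).
#'
#' @param ecv target myocardial ECV as a fraction in `[0, 1)`.
#' @param hematocrit hematocrit fraction in `(0, 1)`.
#' @param t1_myo_pre,t1_blood_pre,t1_blood_post T1 values in ms.
#' @return Post-contrast myocardial T1 in ms.
#' @examples
#' t1_post_from_ecv(0.25, 0.42, 1000, 1500, 300)
#' @export
t1_post_from_ecv <- function(ecv, hematocrit, t1_myo_pre, t1_blood_pre,
                             t1_blood_post) {
  stopifnot(ecv >= 0, ecv < 1, hematocrit > 0, hematocrit < 1,
            t1_myo_pre > 0, t1_blood_pre > 0, t1_blood_post > 0)
  dr1_blood <- delta_r1(t1_blood_pre, t1_blood_post)
  if (dr1_blood <= 0)
    stop("blood dR1 must be positive (post-contrast blood T1 must be shorter)")
  dr1_myo <- ecv / (1 - hematocrit) * dr1_blood
  1 / (1 / t1_myo_pre + dr1_myo)
}

# tissue label map: 0 background, 1 blood, 2 myocardium
phantom_labels <- function(phantom) {
  nr <- phantom$grid_shape[1]; nc <- phantom$grid_shape[2]
  y <- matrix(seq_len(nr), nr, nc) - phantom$blood_center[1]
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - phantom$blood_center[2]
  r <- sqrt(y^2 + x^2)
  lab <- matrix(0L, nr, nc)
  lab[r <= phantom$blood_radius] <- 1L
  lab[r >= phantom$myo_inner_radius & r <= phantom$myo_outer_radius] <- 2L
  lab
}

phantom_t1_map <- function(phantom, contrast_phase = c("pre", "post")) {
  contrast_phase <- match.arg(contrast_phase)
  lab <- phantom_labels(phantom)
  if (contrast_phase == "pre") {
    vals <- c(phantom$background_t1, phantom$t1_blood_pre, phantom$t1_myo_pre)
  } else {
    t1_myo_post <- t1_post_from_ecv(phantom$ecv_myo, phantom$hematocrit,
                                    phantom$t1_myo_pre, phantom$t1_blood_pre,
                                    phantom$t1_blood_post)
    vals <- c(phantom$background_t1, phantom$t1_blood_post, t1_myo_post)
  }
  matrix(vals[lab + 1L], nrow(lab), ncol(lab))
}

# proton density with a smooth deterministic shading so that tissue
# interiors carry intensity gradients (coil-profile surrogate); this is
# what makes intensity-based registration well-posed away from edges
phantom_pd_map <- function(phantom) {
  lab <- phantom_labels(phantom)
  pd <- phantom$proton_density
  a <- matrix(c(pd[["background"]], pd[["blood"]],
                pd[["myocardium"]])[lab + 1L], nrow(lab), ncol(lab))
  nr <- nrow(a); nc <- ncol(a)
  y <- matrix(seq_len(nr) / nr, nr, nc)
  x <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  shade <- 1 + phantom$shading_amplitude *
    (0.6 * sin(2 * pi * y) * cos(2 * pi * x) + 0.4 * (x + y - 1))
  a * shade
}

# draw per-image deformation fields from a motion_spec (seeded)
motion_fields <- function(motion, shape, n) {
  tr <- motion$per_image_translation
  fields <- vector("list", n)
  with_seed(motion$seed, {
    if (is.null(tr)) {
      tr <- matrix(0, n, 2)
      if (motion$drift_amplitude > 0) {
        for (k in 1:2) {
          raw <- cumsum(rnorm(n))
          raw <- raw - raw[1]
          m <- max(abs(raw))
          if (m > 0) raw <- raw / m * motion$drift_amplitude
          tr[, k] <- raw * runif(1, 0.5, 1)
        }
      }
    }
    for (i in seq_len(n)) {
      dy <- matrix(tr[i, 1], shape[1], shape[2])
      dx <- matrix(tr[i, 2], shape[1], shape[2])
      if (motion$nonrigid_amplitude > 0) {
        for (k in 1:2) {
          w <- .cpp_gauss_smooth(matrix(rnorm(prod(shape)), shape[1]),
                                 motion$nonrigid_smoothness)
          m <- max(abs(w))
          if (m > 0) w <- w / m * motion$nonrigid_amplitude
          if (k == 1) dy <- dy + w else dx <- dx + w
        }
      }
      fields[[i]] <- deformation_field(dy, dx, provenance = "simulated")
    }
  })
  fields
}

#' Simulate a MOLLI acquisition of the phantom
#'
#' Generates one magnitude image per inversion time from the ideal
#' three-parameter inversion-recovery model `|A - B exp(-TI/T1*)|` with
#' perfect inversion (`B = 2A`) and `T1* = t1_star_factor * T1`
#' (default factor 1, i.e. no readout bias).  Each image is warped by its
#' per-image respiratory deformation, then magnitude noise is added.
#'
#' @param phantom a [phantom_spec()].
#' @param schedule a [build_ti_schedule()] result.
#' @param motion a [motion_spec()]; default identity motion.
#' @param noise_sd standard deviation of the noise in the units of the
#'   proton density `A` (default 0.02, i.e. SNR 50 at `A = 1`).
#' @param seed integer seed for the noise (and, combined with the motion
#'   spec's own seed, the drawn motion).
#' @param contrast_phase simulate the `"pre"` or `"post"` contrast series.
#' @param t1_star_factor optional scalar apparent-T1* factor emulating
#'   readout-driven bias; ground truth stores the true T1.
#' @param noise_model `"gaussian"` (additive on magnitude, then rectified)
#'   or `"rician"`.
#'
#' @return A list with `series` (a [molli_series()]) and `truth`, the
#'   ground-truth list: `t1_map_pre`, `t1_map_post`, `label_map`
#'   (0 background / 1 blood / 2 myocardium), `ecv_map` (%), and
#'   `deformation_per_image`.
#' @export
simulate_molli_series <- function(phantom, schedule,
                                  motion = motion_spec(),
                                  noise_sd = 0.02, seed = 1L,
                                  contrast_phase = c("pre", "post"),
                                  t1_star_factor = 1,
                                  noise_model = c("gaussian", "rician")) {
  contrast_phase <- match.arg(contrast_phase)
  noise_model <- match.arg(noise_model)
  shape <- phantom$grid_shape
  t1 <- phantom_t1_map(phantom, contrast_phase)
  a <- phantom_pd_map(phantom)
  lab <- phantom_labels(phantom)
  ti <- schedule$ti_values
  n <- length(ti)
  fields <- motion_fields(motion, shape, n)
  images <- array(0, dim = c(shape, n))
  t1_star <- t1_star_factor * t1
  for (i in seq_len(n)) {
    img <- abs(a - 2 * a * exp(-ti[i] / t1_star))
    images[, , i] <- warp(img, fields[[i]], interpolation_order = 5L)
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      if (noise_model == "gaussian") {
        images <- abs(images + rnorm(length(images), sd = noise_sd))
      } else {
        images <- sqrt((images + rnorm(length(images), sd = noise_sd))^2 +
                       rnorm(length(images), sd = noise_sd)^2)
      }
    }
  })
  ecv_map <- matrix(NA_real_, shape[1], shape[2])
  ecv_map[lab == 2L] <- phantom$ecv_myo * 100
  ecv_map[lab == 1L] <- (1 - phantom$hematocrit) * 100
  truth <- list(t1_map_pre = phantom_t1_map(phantom, "pre"),
                t1_map_post = phantom_t1_map(phantom, "post"),
                label_map = lab, ecv_map = ecv_map,
                deformation_per_image = fields,
                proton_density = a)
  series <- molli_series(images, ti, phantom$pixel_spacing, contrast_phase,
                         meta = list(heart_rate = schedule$heart_rate,
                                     protocol = schedule$protocol_variant,
                                     noise_sd = noise_sd, seed = seed))
  list(series = series, truth = truth)
}
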