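# coregistration tests run on motion-free series (wrapped as trivial MOCO
# results) so they isolate the breath-hold alignment step

static_moco <- function(sim) ecvmap:::no_moco_result(sim$series)

test_that("matching respiratory positions give a near-identity coreg field", {
  ph <- small_phantom()
  pre <- simulate_molli_series(ph, schedule_60(), noise_sd = 0.01, seed = 1)
  post <- simulate_molli_series(ph, schedule_60(), noise_sd = 0.01, seed = 2,
                                contrast_phase = "post")
  cr <- coregister_pre_post(static_moco(pre), static_moco(post))
  # sub-pixel only: pre blood is ~87% recovered at the longest TI while
  # post blood is fully recovered, so SSD registration shifts the
  # blood-myocardium edge slightly even at identical positions
  expect_lt(mean(ecvmap:::field_magnitude(cr$coreg_field)), 0.5)
  # ECV with and without the (near-identity) co-registration agree closely
  pre_fit <- fit_map(pre$series)
  blood <- segment_blood(pre_fit, post_t1 = cr$post_fit)
  hct <- ph$hematocrit
  e_coreg <- compute_ecv(pre_fit, cr$post_fit, blood, hct)
  post_fit0 <- fit_map(post$series)
  blood0 <- segment_blood(pre_fit, post_t1 = post_fit0)
  e_plain <- compute_ecv(pre_fit, post_fit0, blood0, hct)
  myo <- pre$truth$label_map == 2
  expect_lt(abs(median(e_coreg$ecv[myo], na.rm = TRUE) -
                median(e_plain$ecv[myo], na.rm = TRUE)), 0.3)
})

test_that("a 5 px inter-breath-hold shift is corrected", {
  ph <- small_phantom()
  pre <- simulate_molli_series(ph, schedule_60(), noise_sd = 0.01, seed = 3)
  post <- simulate_molli_series(
    ph, schedule_60(),
    motion_spec(per_image_translation = matrix(rep(c(5, 0), each = 8), 8, 2)),
    noise_sd = 0.01, seed = 4, contrast_phase = "post")
  pre_fit <- fit_map(pre$series)
  myo <- pre$truth$label_map == 2
  truth_ecv <- ph$ecv_myo * 100
  cr <- coregister_pre_post(static_moco(pre), static_moco(post))
  blood <- segment_blood(pre_fit, post_t1 = cr$post_fit)
  e1 <- compute_ecv(pre_fit, cr$post_fit, blood, ph$hematocrit)
  expect_lt(abs(median(e1$ecv[myo], na.rm = TRUE) - truth_ecv), 1)
  # skipping co-registration leaves a gross artifact (rim of wrong ECV)
  post_fit0 <- fit_map(post$series)
  e0 <- compute_ecv(pre_fit, post_fit0, blood, ph$hematocrit)
  expect_gt(abs(median(e0$ecv[myo], na.rm = TRUE) - truth_ecv),
            abs(median(e1$ecv[myo], na.rm = TRUE) - truth_ecv))
  expect_gt(sd(e0$ecv[myo], na.rm = TRUE), sd(e1$ecv[myo], na.rm = TRUE))
})

test_that("long-TI pre/post contrast similarity premise holds", {
  ph <- small_phantom()
  pre <- simulate_molli_series(ph, schedule_60(), noise_sd = 0.01, seed = 5)
  post <- simulate_molli_series(ph, schedule_60(), noise_sd = 0.01, seed = 6,
                                contrast_phase = "post")
  a <- pre$series$images[, , 5]    # longest TI in the 5-3 ordering
  b <- post$series$images[, , 5]
  expect_gt(stats::cor(as.vector(a), as.vector(b)), 0.95)
})

test_that("composite single warp beats sequential double warp vs truth", {
  # analytic truth: fractional translations compose exactly, so the truth
  # image is a single interpolation while the double-warp path takes two
  set.seed(8)
  wins <- 0
  n_trials <- 10
  n <- 70
  gy <- matrix(seq_len(n), n, n)
  gx <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (k in seq_len(n_trials)) {
    # analytic image: mixture of Gaussian blobs, evaluable anywhere
    ctr <- matrix(runif(12, 10, n - 10), 6, 2)
    wdt <- runif(6, 3, 8)
    g <- function(y, x) {
      v <- 0
      for (b in 1:6)
        v <- v + exp(-((y - ctr[b, 1])^2 + (x - ctr[b, 2])^2) /
                       (2 * wdt[b]^2))
      v
    }
    img <- g(gy, gx)
    t1v <- runif(2, -3, 3); t2v <- runif(2, -3, 3)
    f1 <- deformation_field(matrix(t1v[1], n, n), matrix(t1v[2], n, n))
    f2 <- deformation_field(matrix(t2v[1], n, n), matrix(t2v[2], n, n))
    single <- warp(img, compose_fields(f1, f2), 5)
    double <- warp(warp(img, f1, 5), f2, 5)
    truth <- g(gy + t1v[1] + t2v[1], gx + t1v[2] + t2v[2])
    interior <- matrix(FALSE, n, n); interior[11:60, 11:60] <- TRUE
    e_single <- sqrt(mean((single[interior] - truth[interior])^2))
    e_double <- sqrt(mean((double[interior] - truth[interior])^2))
    if (e_single <= e_double) wins <- wins + 1
  }
  expect_gte(wins, 0.9 * n_trials)
})

test_that("shape and spacing mismatches are rejected", {
  ph <- small_phantom()
  pre <- simulate_molli_series(ph, schedule_60(), noise_sd = 0, seed = 1)
  ph2 <- phantom_spec(grid_shape = c(48L, 48L), blood_radius = 8,
                      myo_inner_radius = 10, myo_outer_radius = 14)
  post <- simulate_molli_series(ph2, schedule_60(), noise_sd = 0, seed = 2,
                                contrast_phase = "post")
  expect_error(coregister_pre_post(static_moco(pre), static_moco(post)),
               "shape")
})
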