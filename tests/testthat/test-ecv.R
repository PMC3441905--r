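# minimal constant-valued T1 map results for arithmetic-level tests
flat_t1 <- function(t1, shape = c(24, 24), ok = TRUE) {
  m <- matrix(t1, shape[1], shape[2])
  ecvmap:::t1_map_result(a_map = matrix(1, shape[1], shape[2]),
                         b_map = matrix(2, shape[1], shape[2]),
                         t1_star_map = m, t1_map = m,
                         rss_map = matrix(0, shape[1], shape[2]),
                         fit_ok_mask = matrix(ok, shape[1], shape[2]))
}

test_that("delta_r1 and relaxivity arithmetic", {
  expect_equal(delta_r1(1500, 300), 0.00266667, tolerance = 1e-5)
  expect_equal(delta_r1(1000, 450), 0.00122222, tolerance = 1e-5)
  expect_equal(delta_r1(880, 880), 0)
  expect_error(delta_r1(-1, 300))
  expect_equal(gd_delta_r1(1), 4.5)
  expect_equal(gd_delta_r1(0), 0)
  expect_equal(gd_delta_r1(0.5), 2.25)
})

test_that("normal_range is mean +/- 2 SD", {
  expect_equal(unname(normal_range(25.4, 2.5)), c(20.4, 30.4))
  expect_equal(unname(normal_range(7, 0)), c(7, 7))
  expect_equal(unname(normal_range(30, 4)), c(22, 38))
  expect_error(normal_range(25, -1))
})

test_that("blood segmentation finds the phantom blood pool exactly", {
  ph <- small_phantom()
  sim <- simulate_molli_series(ph, schedule_60(), noise_sd = 0.01, seed = 11)
  simp <- simulate_molli_series(ph, schedule_60(), noise_sd = 0.01, seed = 12,
                                contrast_phase = "post")
  pre_fit <- fit_map(sim$series)
  post_fit <- fit_map(simp$series)
  blood <- segment_blood(pre_fit, post_t1 = post_fit)
  lab <- sim$truth$label_map
  expect_true(all(lab[blood$mask] == 1))          # mask inside blood label
  expect_lt(abs(blood$t1_blood_pre - ph$t1_blood_pre), 5)
  expect_lt(abs(blood$t1_blood_post - ph$t1_blood_post), 5)
  expect_gte(blood$n_pixels, 20)
})

test_that("degenerate maps yield an actionable segmentation error", {
  expect_error(segment_blood(flat_t1(1000)), "manually")
  # one isolated supra-threshold pixel is removed as noise
  one <- flat_t1(1000)
  one$t1_map[12, 12] <- 1600
  expect_error(segment_blood(one), "manually")
})

test_that("compute_ecv reproduces hand-evaluated values", {
  pre <- flat_t1(1000); post <- flat_t1(450)
  blood <- structure(list(mask = matrix(FALSE, 24, 24), t1_blood_pre = 1500,
                          t1_blood_post = 300, n_pixels = 10,
                          threshold_used = 1250, erosion_radius = 1),
                     class = "blood_mask")
  e <- compute_ecv(pre, post, blood, 0.42)
  expect_equal(e$ecv[1, 1], 26.6, tolerance = 2e-3)
  expect_equal(e$delta_r1_blood, 0.00266667, tolerance = 1e-5)
  # no T1 change -> 0%
  e0 <- compute_ecv(pre, flat_t1(1000), blood, 0.42)
  expect_equal(e0$ecv[1, 1], 0)
  # blood-like pixel -> (1 - hct) * 100
  eb <- compute_ecv(flat_t1(1500), flat_t1(300), blood, 0.42)
  expect_equal(eb$ecv[1, 1], 58, tolerance = 1e-9)
  # mislabeled series rejected
  blood_bad <- blood; blood_bad$t1_blood_pre <- 300
  blood_bad$t1_blood_post <- 1500
  expect_error(compute_ecv(pre, post, blood_bad, 0.42), "mislabeled")
})

test_that("partition coefficient relates to ECV by (1 - hct)", {
  pre <- flat_t1(1000); post <- flat_t1(450)
  blood <- structure(list(mask = matrix(FALSE, 24, 24), t1_blood_pre = 1500,
                          t1_blood_post = 300, n_pixels = 10,
                          threshold_used = 1250, erosion_radius = 1),
                     class = "blood_mask")
  lam <- partition_coefficient_map(pre, post, blood)
  expect_equal(lam$lambda[1, 1], 0.4583, tolerance = 1e-4)
  # blood-like pixel has lambda 1
  lamb <- partition_coefficient_map(flat_t1(1500), flat_t1(300), blood)
  expect_equal(lamb$lambda[1, 1], 1, tolerance = 1e-12)
  # identity: ECV = (1 - hct) * lambda * 100
  for (hct in c(0.3, 0.42, 0.55)) {
    e <- compute_ecv(pre, post, blood, hct)
    expect_equal(e$ecv[2, 2], (1 - hct) * lam$lambda[2, 2] * 100,
                 tolerance = 1e-10)
  }
})

test_that("ECV scales exactly with (1 - hct) and clips invalid pixels", {
  pre <- flat_t1(1000); post <- flat_t1(450)
  blood <- structure(list(mask = matrix(FALSE, 24, 24), t1_blood_pre = 1500,
                          t1_blood_post = 300, n_pixels = 10,
                          threshold_used = 1250, erosion_radius = 1),
                     class = "blood_mask")
  a <- compute_ecv(pre, post, blood, 0.35)
  b <- compute_ecv(pre, post, blood, 0.50)
  expect_equal(a$ecv / b$ecv,
               matrix((1 - 0.35) / (1 - 0.50), 24, 24), tolerance = 1e-12)
  # a pixel with negative raw ECV (post T1 longer than pre) is invalid
  post2 <- flat_t1(450); post2$t1_map[3, 3] <- 1200
  e <- compute_ecv(pre, post2, blood, 0.42)
  expect_false(e$valid_mask[3, 3])
  expect_true(is.na(e$ecv[3, 3]))
  expect_lt(e$ecv_raw[3, 3], 0)     # raw value preserved
  # not-ok fits propagate to invalid ECV
  pre2 <- flat_t1(1000); pre2$fit_ok_mask[4, 4] <- FALSE
  expect_false(compute_ecv(pre2, post, blood, 0.42)$valid_mask[4, 4])
})
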