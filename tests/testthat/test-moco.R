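test_that("registering an image to itself gives a near-identity field", {
  sim <- simulate_molli_series(small_phantom(), schedule_60(),
                               noise_sd = 0.01, seed = 2)
  img <- sim$series$images[, , 8]
  f <- register_nonrigid(img, img)
  expect_lt(mean(ecvmap:::field_magnitude(f)), 0.05)
})

test_that("a known translation is recovered over the myocardial ring", {
  sim <- simulate_molli_series(small_phantom(), schedule_60(),
                               noise_sd = 0, seed = 2)
  moving <- sim$series$images[, , 8]
  shift <- deformation_field(matrix(3, 64, 64), matrix(-2, 64, 64))
  fixed <- warp(moving, shift, 5)   # fixed(x) = moving(x + (3, -2))
  f <- register_nonrigid(moving, fixed)
  ring <- sim$truth$label_map == 2
  expect_lt(translation_error(f, 3, -2, ring), 0.3)
})

test_that("degenerate and structureless pairs stay bounded", {
  expect_warning(f <- register_nonrigid(matrix(1, 32, 32), matrix(1, 32, 32)),
                 "degenerate")
  expect_true(all(ecvmap:::field_magnitude(f) == 0))
  set.seed(6)
  a <- matrix(rnorm(32 * 32), 32); b <- matrix(rnorm(32 * 32), 32)
  expect_warning(f2 <- register_nonrigid(a, b), "low-confidence")
  expect_true(f2$low_confidence)
  expect_lt(mean(ecvmap:::field_magnitude(f2)), 3)  # no random-walk explosion
})

test_that("motion-free series passes through MOCO almost unchanged", {
  # residual sub-pixel fields remain on the frames whose contrast is most
  # sensitive to the crude T1 seed (near the blood null); the SSD-demons
  # backend cannot tell that mismatch from motion, so the bound here is
  # sub-pixel, not interpolation-exact (see the methods vignette)
  sim <- simulate_molli_series(small_phantom(), schedule_60(),
                               noise_sd = 0.01, seed = 4)
  mc <- moco_series(sim$series)
  for (f in mc$fields)
    expect_lt(mean(ecvmap:::field_magnitude(f)), 0.6)
  rel <- sqrt(mean((mc$corrected$images - sim$series$images)^2)) /
    max(sim$series$images)
  expect_lt(rel, 0.03)
})

test_that("MOCO corrects translated images and improves the fit", {
  ph <- small_phantom()
  tr <- cbind(c(0, 1.5, -2, 3, 2, -3, 2, 0.5),
              c(0, -1, 2, -3, 1, 2, -2, 1))
  sim <- simulate_molli_series(ph, schedule_60(),
                               motion_spec(per_image_translation = tr),
                               noise_sd = 0.02, seed = 7)
  mc <- moco_series(sim$series)
  lab <- sim$truth$label_map
  tissue <- lab > 0
  # accumulated fields should map each image onto the longest-TI anchor
  anchor <- tr[which.max(schedule_60()$ti_values), ]
  derr <- mean(vapply(seq_len(8), function(i)
    translation_error(mc$fields[[i]], anchor[1] - tr[i, 1],
                      anchor[2] - tr[i, 2], tissue), 0))
  expect_lt(derr, 0.8)
  # T1 error over myocardium reduced by at least 50%
  fit0 <- fit_map(sim$series)
  myo <- lab == 2
  truth <- sim$truth$t1_map_pre
  err0 <- median(abs(fit0$t1_map[myo] - truth[myo]), na.rm = TRUE)
  err1 <- median(abs(mc$fit$t1_map[myo] - truth[myo]), na.rm = TRUE)
  expect_lt(err1, 0.5 * err0)
  # goodness-of-fit over myocardium improves after MOCO
  expect_lt(sum(mc$fit$rss_map[myo]), sum(fit0$rss_map[myo]))
})

test_that("MOCO is deterministic", {
  sim <- simulate_molli_series(
    small_phantom(), schedule_60(),
    motion_spec(per_image_translation = cbind(rep(c(1, -1), 4),
                                              rep(c(-1, 1), 4))),
    noise_sd = 0.02, seed = 9)
  a <- moco_series(sim$series, n_iterations = 1)
  b <- moco_series(sim$series, n_iterations = 1)
  for (i in seq_len(8)) {
    expect_identical(a$fields[[i]]$dy, b$fields[[i]]$dy)
    expect_identical(a$fields[[i]]$dx, b$fields[[i]]$dx)
  }
  expect_identical(a$fit$t1_map, b$fit$t1_map)
})
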