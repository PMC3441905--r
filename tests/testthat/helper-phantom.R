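# Shared fixtures: a small fast phantom, and an independent brute-force
# grid-search oracle for the pixel fitter (enumeration over T1* with
# sign-iterated linear least squares for A and B at each grid point).

small_phantom <- function(...) {
  phantom_spec(grid_shape = c(64L, 64L), blood_radius = 8,
               myo_inner_radius = 10, myo_outer_radius = 15, ...)
}

schedule_60 <- function(variant = "5-3") build_ti_schedule(variant, 60)

# oracle: dense T1* grid; per grid point the best (A, B) of the magnitude
# model are found by iterating sign assignments of (A - B e) and solving
# the resulting linear least-squares problem in closed form
oracle_fit <- function(signal, ti, t1_grid = seq(50, 5000, by = 1)) {
  E <- exp(-outer(as.numeric(ti), as.numeric(t1_grid), "/"))  # nTI x G
  n <- length(signal)
  Se <- colSums(E); See <- colSums(E^2)
  A <- rep(max(signal), ncol(E)); B <- 2 * A
  for (k in 1:12) {
    M <- matrix(A, n, length(A), byrow = TRUE) -
      E * matrix(B, n, length(B), byrow = TRUE)
    sg <- ifelse(M >= 0, 1, -1)
    y <- sg * signal                      # recycles signal down columns
    Sy <- colSums(y); Sey <- colSums(E * y)
    det <- n * See - Se^2
    A <- (Sy * See - Se * Sey) / det
    B <- (Se * Sy - n * Sey) / det
  }
  M <- matrix(A, n, length(A), byrow = TRUE) -
    E * matrix(B, n, length(B), byrow = TRUE)
  rss <- colSums((signal - abs(M))^2)
  i <- which.min(rss)
  list(A = A[i], B = B[i], t1_star = t1_grid[i], rss = rss[i])
}

# simulate a seeded noisy pixel from the ideal model
noisy_pixel <- function(A, B, t1_star, ti, noise_sd, seed) {
  set.seed(seed)
  abs(abs(A - B * exp(-ti / t1_star)) + rnorm(length(ti), sd = noise_sd))
}

# exact-model signal
ideal_pixel <- function(A, B, t1_star, ti) abs(A - B * exp(-ti / t1_star))

# mean displacement error of a recovered field against a known translation
translation_error <- function(field, dy, dx, mask) {
  mean(sqrt((field$dy[mask] - dy)^2 + (field$dx[mask] - dx)^2))
}
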