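# Power spectra, autocorrelation repeats, the Bessel meridional scan,
# layer-line picking and P = n * h indexing.

make_ps <- function(power, pixel_size) {
  structure(list(power = power,
                 reciprocal_pixel = c(1 / (nrow(power) * pixel_size),
                                      1 / (ncol(power) * pixel_size)),
                 pixel_size = pixel_size, meridian_axis = 2L,
                 n_images = 1L, dim = dim(power)),
            class = "power_spectrum")
}

test_that("averaged power spectra satisfy the Fourier identities", {
  # a delta function has a flat spectrum
  img <- matrix(0, 32, 32); img[5, 9] <- 1
  ps <- average_power_spectrum(array(img, c(32, 32, 1)), pixel_size = 2)
  expect_lt(diff(range(ps$power)), 1e-12)
  # a vertical cosine grating of period d px peaks at 1/d on the axial axis
  d <- 8; box <- 64L
  v <- matrix(rep(cos(2 * pi * (1:box) / d), each = box), box, box)
  psv <- average_power_spectrum(array(v, c(box, box, 1)), pixel_size = 1)
  pk <- which(psv$power == max(psv$power[, -33]), arr.ind = TRUE)
  ax <- abs(vifhelix:::ps_axial_coords(psv)[pk[, 2]])
  expect_equal(unique(round(ax, 9)), 1 / d)
  # Parseval: sum of the spectrum equals the image energy
  set.seed(1)
  r <- matrix(stats::rnorm(box^2), box, box)
  psr <- average_power_spectrum(array(r, c(box, box, 1)), pixel_size = 1)
  expect_equal(sum(psr$power), sum(r^2), tolerance = 1e-9)
  # Friedel symmetry of a real image's spectrum
  p <- psr$power[-1, -1]
  expect_lt(max(abs(p - p[nrow(p):1, ncol(p):1])), 1e-6 * max(p))
  expect_error(average_power_spectrum(array(0, c(8, 8, 0)), pixel_size = 1),
               "empty")
})

test_that("autocorrelation finds the fundamental repeat", {
  # cosine stripes of period 186 A at 1 A/px
  box <- 512L
  img <- matrix(rep(cos(2 * pi * (1:box) / 186), each = 64), 64, box)
  ac <- autocorrelation_repeat(img, pixel_size = 1)
  expect_false(ac$aperiodic)
  expect_rel_equal(ac$repeat_A, 186, 0.01)
  # constant image: aperiodic
  expect_true(autocorrelation_repeat(matrix(1, 64, 256), 1)$aperiodic)
  # noiseless projection of a commensurate filament repeats at the pitch
  pC <- params_from_units(5, 42.5)
  mC <- build_filament_model(params = pC, n_tetramers = 48)
  img2 <- project_model(mC, 110L, 560L, 3.44,
                        center_z = mean(range(mC$beads$z)), thickness = 220)
  ac2 <- autocorrelation_repeat(img2, 3.44)
  expect_rel_equal(ac2$repeat_A, pC$pitch, 0.05)
})

test_that("the J0 template has the documented scaling", {
  expect_equal(bessel_meridional_template(55, 0), 1)
  # first zero at 2.4048 / (2 pi x 55) ~ 1/143.7 A
  z <- stats::uniroot(function(r) bessel_meridional_template(55, r),
                      c(0.004, 0.01), tol = 1e-12)$root
  expect_rel_equal(1 / z, 143.7, 0.001)
  # a synthetic spectrum whose single row is the template scores 1 there
  box <- 128L
  lat <- vifhelix:::fft_freqs(box) / 2
  pw <- matrix(1e-6, box, box)
  j <- 71L  # axial coordinate 6/256 = 0.0234 1/A, inside the scan band
  pw[, j] <- (bessel_meridional_template(55, lat) + 1.5)^2
  ps <- make_ps(pw, 2)
  sc <- scan_meridional_bessel(ps, 55, band = c(1 / 69, 1 / 30))
  expect_equal(which.min(abs(sc$row_positions - sc$best)),
               which(abs(sc$row_positions -
                           vifhelix:::ps_axial_coords(ps)[j]) < 1e-12))
})

test_that("the meridional scan recovers the rise of a noiseless filament", {
  m <- segment_model(40)
  st <- project_segments(m, imaging_params(noise_sigma = 0, seed = 1),
                         n_segments = 40, spacing = 42.5)
  ps <- average_power_spectrum(st)
  sc <- scan_meridional_bessel(ps, 55, c(1 / 69, 1 / 30))
  expect_true(sc$reliable)
  expect_lt(abs(sc$best - 1 / 42.5), ps$reciprocal_pixel[2])
  expect_error(scan_meridional_bessel(ps, 55, c(1 / 5, 1 / 2)), "Nyquist")
})

test_that("a white-noise spectrum yields an unreliable scan", {
  set.seed(99)
  hits <- vapply(1:5, function(i) {
    imgs <- array(stats::rnorm(110 * 110 * 10), c(110, 110, 10))
    ps <- average_power_spectrum(imgs, pixel_size = 3.44)
    scan_meridional_bessel(ps, 55, c(1 / 69, 1 / 30))$reliable
  }, logical(1))
  expect_lte(sum(hits), 1L)
})

test_that("layer-line picking returns constructed impulses exactly", {
  box <- 256L
  pw <- matrix(1e-8, 64, box)
  j1 <- 129L + 5L; j2 <- 129L + 24L
  pw[, j1] <- 4; pw[, j2] <- 2
  ps <- make_ps(pw, 2)
  pk <- pick_layer_lines(ps, band = c(1 / 400, 1 / 10),
                         min_prominence = 0.1)
  ax <- vifhelix:::ps_axial_coords(ps)
  expect_equal(pk$positions, ax[c(j1, j2)], tolerance = 1e-9)
  # prominence 1.0 keeps at most the global maximum
  pk1 <- pick_layer_lines(ps, band = c(1 / 400, 1 / 10),
                          min_prominence = 1.0)
  expect_lte(length(pk1$positions), 1L)
  # empty result allowed
  flat <- make_ps(matrix(1, 64, box), 2)
  expect_length(pick_layer_lines(flat, band = c(1 / 400, 1 / 10))$positions,
                0L)
})

test_that("the pitch layer line appears in a long-range spectrum", {
  ps <- fixture("long_ps_default", long_spectrum(vif_params()))
  pk <- pick_layer_lines(ps, band = c(1 / 280, 1 / 150),
                         min_prominence = 0.2)
  expect_gte(length(pk$positions), 1L)
  # lowest-resolution pick near the 207.5 A pitch of the default model
  expect_lt(abs(pk$positions[1] - 1 / 207.5), ps$reciprocal_pixel[2])
})

test_that("indexing the printed layer-line pairs is exact least squares", {
  P <- c(207.4, 195.9, 185.6, 176.3)
  h <- c(42.5, 40.1, 37.9, 36.3)
  idx <- index_layer_lines(P, h)
  # oracle: independent 1D numerical minimization of the residual sum
  oracle <- stats::optimize(function(n) sum((P - n * h)^2), c(3, 7),
                            tol = 1e-10)$minimum
  expect_equal(idx$n, oracle, tolerance = 1e-7)
  expect_equal(idx$n, 4.880393, tolerance = 1e-6)
  expect_equal(idx$residuals_A, P - idx$n * h)
  # single exact pair
  i2 <- index_layer_lines(210, 42)
  expect_equal(i2$n, 5)
  expect_equal(i2$params$twist, 72)
  # exact construction: P = 4.5 h -> n = 4.5, zero residuals
  h3 <- c(40, 38, 36)
  i3 <- index_layer_lines(4.5 * h3, h3)
  expect_equal(i3$n, 4.5)
  expect_equal(max(abs(i3$residuals_A)), 0)
  # scale equivariance
  i4 <- index_layer_lines(3 * P, 3 * h)
  expect_equal(i4$n, idx$n)
  expect_error(index_layer_lines(P, h[1:3]), "equal length")
  expect_error(index_layer_lines(c(-1, 2), c(1, 1)), "positive")
})

test_that("an exact five-fold filament puts the meridional on layer 5", {
  p5 <- params_from_units(5, 37)
  ps <- fixture("long_ps_fivefold", long_spectrum(p5))
  picks <- pick_layer_lines(ps, band = c(1 / 400, 1 / 28),
                            min_prominence = 0.05)
  sc <- scan_meridional_bessel(ps, 55, c(1 / 69, 1 / 30))
  expect_gte(length(picks$positions), 5L)
  # layer lines sit at multiples of 1/pitch
  orders <- round(picks$positions * p5$pitch)
  expect_equal(orders[1:5], 1:5)
  expect_lt(max(abs(picks$positions[1:5] - orders[1:5] / p5$pitch)),
            ps$reciprocal_pixel[2])
  # the meridional reflection falls on the 5th layer line
  nearest <- which.min(abs(picks$positions - sc$best))
  expect_equal(orders[nearest], 5)
})
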