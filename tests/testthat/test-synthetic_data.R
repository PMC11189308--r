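# The synthetic generator: projections with exact transform bookkeeping,
# density rendering, missing wedge, bent paths, MRC/CSV round trips.

test_that("projection equals the analytic Gaussian-blob line integral", {
  # tiny model, brute-force double-loop oracle
  g <- tetramer_geometry()
  m <- build_filament_model(g, n_tetramers = 1)
  m$beads <- m$beads[seq(1, nrow(m$beads), by = 17), ]
  nx <- 32L; ny <- 48L; px <- 3
  img <- project_model(m, nx, ny, px, center_z = 0, thickness = Inf)
  oracle <- matrix(0, nx, ny)
  s <- g$bead_sigma
  cx <- floor(nx / 2) + 1L; cy <- floor(ny / 2) + 1L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    u <- (i - cx) * px; v <- (j - cy) * px
    oracle[i, j] <- sum(m$beads$mass * px^2 / (2 * pi * s^2) *
                          exp(-((u - m$beads$x)^2 + (v - m$beads$z)^2) /
                                (2 * s^2)))
  }
  expect_lt(max(abs(img - oracle)) / max(oracle), 1e-5)
})

test_that("segment generation is deterministic and exactly recorded", {
  m <- segment_model(6)
  im <- imaging_params(noise_sigma = 0.4, seed = 42)
  s1 <- project_segments(m, im, n_segments = 6, spacing = 42.5)
  s2 <- project_segments(m, im, n_segments = 6, spacing = 42.5)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$records, s2$records)
  # a different seed changes the stack
  s3 <- project_segments(m, imaging_params(noise_sigma = 0.4, seed = 43),
                         n_segments = 6, spacing = 42.5)
  expect_false(identical(s1$images, s3$images))
  # noiseless segment equals the recorded transform applied to the truth
  s0 <- project_segments(m, imaging_params(noise_sigma = 0, seed = 7),
                         n_segments = 3, spacing = 42.5)
  for (i in 1:3)
    expect_equal(s0$images[, , i], segment_truth_projection(s0, i),
                 tolerance = 1e-12)
  expect_error(project_segments(m, im, n_segments = 6, spacing = -1),
               "positive")
  expect_error(project_segments(m, im, n_segments = 500, spacing = 42.5),
               "too short")
})

test_that("density rendering conserves mass and is linear", {
  m <- build_filament_model(n_tetramers = 2)
  map <- render_density_map(m, voxel_size = 4)
  expect_rel_equal(sum(map$grid), sum(m$beads$mass), 0.005)
  m2 <- m
  m2$beads$mass <- 2 * m2$beads$mass
  map2 <- render_density_map(m2, voxel_size = 4)
  expect_equal(map2$grid, 2 * map$grid, tolerance = 1e-12)
  # a model that does not fit raises
  expect_error(render_density_map(m, voxel_size = 4, box = 16L), "box")
  # empty model renders an empty grid
  me <- m
  me$beads <- me$beads[0, ]
  expect_true(all(render_density_map(me, 4, box = 16L)$grid == 0))
})

test_that("the missing wedge zeroes the unsampled region and idempotes", {
  m <- build_filament_model(n_tetramers = 2)
  map <- render_density_map(m, voxel_size = 6)
  # full tilt range: map unchanged
  full <- apply_missing_wedge(map, c(-90, 90))
  expect_lt(max(abs(full$grid - map$grid)) / max(abs(map$grid)), 1e-6)
  w <- apply_missing_wedge(map, c(-60, 60))
  expect_equal(w$wedge, c(-60, 60))
  # wedge region of the spectrum is empty
  Fw <- stats::fft(w$grid)
  d <- dim(w$grid)
  ky <- vifhelix:::fft_freqs_unshifted(d[2])
  kz <- vifhelix:::fft_freqs_unshifted(d[3])
  ang <- atan2(rep(kz, each = d[2]), rep(ky, times = d[3])) * 180 / pi
  ang <- ifelse(ang > 90, ang - 180, ifelse(ang <= -90, ang + 180, ang))
  bad <- abs(ang) > 60.5 & !(rep(ky, times = d[3]) == 0 &
                               rep(kz, each = d[2]) == 0)
  mx <- max(Mod(stats::fft(map$grid)))
  for (i in c(1L, 3L))
    expect_lt(max(Mod(Fw[i, , ])[bad]), 1e-6 * mx)
  # idempotence
  w2 <- apply_missing_wedge(w, c(-60, 60))
  expect_equal(w2$grid, w$grid, tolerance = 1e-9)
  expect_error(apply_missing_wedge(map, c(60, -60)), "tilt_range")
})

test_that("a wedge elongates a point source along z more than x", {
  pt <- array(0, c(32, 32, 32)); pt[17, 17, 17] <- 1
  pw <- apply_missing_wedge(density_map(pt, 1), c(-60, 60))
  g <- abs(pw$grid)
  thr <- 0.1 * max(g)
  zext <- sum(g[17, 17, ] > thr)
  xext <- sum(g[, 17, 17] > thr)
  expect_gt(zext / xext, 1)
})

test_that("bending preserves arc structure and guards curvature", {
  p <- params_from_units(5, 42.5)
  m <- build_filament_model(params = p, n_tetramers = 10)
  zmin <- min(m$beads$z); ext <- diff(range(m$beads$z))
  # straight path: model unchanged
  ms <- bend_path(m, cbind(0, 0, seq(zmin, zmin + 1.02 * ext,
                                     length.out = 12)))
  expect_lt(max(abs(as.matrix(ms$beads[, 1:3]) -
                      as.matrix(m$beads[, 1:3]))), 1e-9)
  # gentle arc: end-to-end shorter than contour, contour preserved
  q <- seq(0, 1.05 * ext, length.out = 40); R <- 5000
  mq <- bend_path(m, cbind(R - R * cos(q / R), 0, R * sin(q / R)))
  i1 <- which.min(m$beads$z); i2 <- which.max(m$beads$z)
  e2e <- sqrt(sum((mq$beads[i2, c("x", "y", "z")] -
                     mq$beads[i1, c("x", "y", "z")])^2))
  expect_lt(e2e, ext)
  # chord of a circular arc: 2 R sin(L / 2R); axis beads follow it
  expect_rel_equal(e2e, 2 * R * sin(ext / (2 * R)), 0.01)
  # over-tight curvature refuses
  zz <- seq(0, 2000, length.out = 50)
  expect_error(bend_path(m, cbind(80 * sin(zz * 2 * pi / 300), 0, zz)),
               "curvature")
  expect_error(bend_path(m, cbind(0, 0, c(0, 100))), "too short")
})

test_that("an odd protofibril count unbalances the projected walls", {
  asym <- function(npf) {
    m <- build_filament_model(params = params_from_units(npf, 42.5),
                              n_tetramers = 40, n_protofibrils = npf)
    zc <- mean(range(m$beads$z))
    mean(vapply(seq(0, 170, by = 42.5), function(dz)
      wall_asymmetry(project_model(m, 110L, 110L, 3.44,
                                   center_z = zc + dz, thickness = 220)),
      numeric(1)))
  }
  a4 <- asym(4); a5 <- asym(5)
  expect_lt(a4, 0.03)
  expect_gt(a5, 2 * a4)
})

test_that("MRC files round trip and carry a valid MRC2014 header", {
  arr <- array(stats::rnorm(24 * 20 * 16), c(24, 20, 16))
  f <- tempfile(fileext = ".mrc")
  write_mrc(arr, f, voxel_size = 2.5, origin = c(1, -2, 3.5))
  m <- read_mrc(f)
  expect_equal(dim(m$grid), c(24L, 20L, 16L))
  expect_lt(max(abs(m$grid - arr)), 1e-6)
  expect_equal(m$voxel_size, 2.5, tolerance = 1e-6)
  expect_equal(m$origin, c(1, -2, 3.5), tolerance = 1e-6)
  # independent reader (gemmi) agrees on geometry and statistics
  chk <- tryCatch(system2("python", c("-c", shQuote(sprintf(
    "import gemmi; m = gemmi.read_ccp4_map('%s'); import numpy as np; a = np.array(m.grid, copy=False); print(a.shape[0], a.shape[1], a.shape[2], round(float(m.grid.unit_cell.a / a.shape[0]), 6), round(float(a.mean()), 6))",
    f))), stdout = TRUE, stderr = TRUE), error = function(e) NULL)
  if (!is.null(chk) && is.null(attr(chk, "status"))) {
    parts <- strsplit(trimws(chk[length(chk)]), " ")[[1]]
    expect_equal(sort(as.integer(parts[1:3])), c(16L, 20L, 24L))
    expect_equal(as.numeric(parts[4]), 2.5, tolerance = 1e-5)
    expect_equal(as.numeric(parts[5]), mean(arr), tolerance = 1e-5)
  }
})

test_that("segment stacks round trip through MRC + CSV", {
  m <- segment_model(4)
  s <- project_segments(m, imaging_params(noise_sigma = 0.2, seed = 5),
                        n_segments = 4, spacing = 42.5)
  pre <- file.path(tempdir(), "stack_rt")
  write_segment_stack(s, pre)
  r <- read_segment_stack(pre)
  expect_equal(dim(r$images), dim(s$images))
  expect_lt(max(abs(r$images - s$images)), 1e-6)
  expect_equal(r$records$psi_deg, s$records$psi_deg, tolerance = 1e-6)
  expect_equal(r$records$arc_A, s$records$arc_A, tolerance = 1e-4)
})

test_that("imaging parameter validation", {
  expect_error(imaging_params(pixel_size = 0), "positive")
  expect_error(imaging_params(box = 33), "even")
  expect_error(imaging_params(noise_sigma = -1), ">= 0")
})
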