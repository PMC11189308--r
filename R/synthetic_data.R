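# Synthetic cryo-EM style data with known ground truth: bead-model
# filaments, noisy 2D projection segments with per-segment transform
# records, 3D density maps, missing-wedge corruption and bent filaments.
# Every stochastic output is a deterministic function of (inputs, seed).

#' Imaging parameters for the synthetic generator
#'
#' @param pixel_size pixel edge, Angstrom (default 3.44, a typical binned
#'   tomography pixel).
#' @param box segment box edge, pixels (even; default 110, i.e. ~38 nm).
#' @param noise_sigma additive white Gaussian noise level, as a fraction of
#'   the RMS of the noiseless signal (default 0 = noiseless).
#' @param projection_thickness thickness of the projected slab, Angstrom
#'   (default 220); beads farther than half this from the filament axis
#'   plane are excluded from the projection.
#' @param seed integer RNG seed recorded in every output.
#' @return List of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size = 3.44, box = 110L, noise_sigma = 0,
                           projection_thickness = 220, seed = 1L) {
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  box <- as.integer(box)
  if (box < 8L || box %% 2L != 0L) stop("'box' must be an even integer >= 8")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (projection_thickness <= 0)
    stop("'projection_thickness' must be positive")
  p <- list(pixel_size = pixel_size, box = box, noise_sigma = noise_sigma,
            projection_thickness = projection_thickness,
            seed = as.integer(seed))
  class(p) <- "imaging_params"
  p
}

#' Build a ground-truth filament bead model
#'
#' Convenience wrapper around [assemble_filament()] that returns the model
#' annotated for imaging: nominal radius and (straight) centerline. The
#' default 30-tetramer, 5-protofibril model is ~190 nm long.
#'
#' @inheritParams assemble_filament
#' @param with_heads if `FALSE`, luminal head beads are omitted.
#' @return Object of class `c("filament_model", "lattice_model")`.
#' @export
build_filament_model <- function(geometry = tetramer_geometry(),
                                 params = vif_params(), n_tetramers = 30L,
                                 n_protofibrils = 5L, with_heads = TRUE,
                                 with_tails = TRUE) {
  m <- assemble_filament(n_tetramers, params, geometry, domains = domain_map(),
                         n_protofibrils = n_protofibrils,
                         with_tails = with_tails)
  if (!with_heads) {
    m$beads <- m$beads[m$beads$domain != "head", ]
    rownames(m$beads) <- NULL
  }
  m$radius <- geometry$filament_radius
  m$path <- NULL
  class(m) <- c("filament_model", "lattice_model")
  m
}

#' Project a bead model into a 2D image
#'
#' Line-integral projection along y of the Gaussian beads within
#' `thickness/2` of the x-z plane, rendered at arbitrary image size. The
#' filament axis (z) maps to the image's vertical axis. This is the
#' deterministic core used by [project_segments()].
#'
#' @param model a `filament_model`/`lattice_model`.
#' @param nx,ny image dimensions in pixels (lateral, axial).
#' @param pixel_size Angstrom per pixel.
#' @param center_z axial coordinate (Angstrom) mapped to the image center.
#' @param thickness projection slab thickness, Angstrom (Inf = all beads).
#' @param psi,dx,dy optional in-plane rotation (degrees) and shift
#'   (pixels) applied to the projected bead coordinates.
#' @return `nx` x `ny` matrix.
#' @export
project_model <- function(model, nx, ny, pixel_size, center_z = NULL,
                          thickness = Inf, psi = 0, dx = 0, dy = 0) {
  b <- model$beads
  if (is.null(center_z)) center_z <- mean(range(b$z))
  keep <- abs(b$y) <= thickness / 2
  b <- b[keep, ]
  u <- b$x
  v <- b$z - center_z
  if (psi != 0) {
    R <- rot2(psi)
    uu <- R[1, 1] * u + R[1, 2] * v
    v <- R[2, 1] * u + R[2, 2] * v
    u <- uu
  }
  u <- u + dx * pixel_size
  v <- v + dy * pixel_size
  splat_gaussians_2d(u, v, b$mass, nx, ny, pixel_size,
                     model$geometry$bead_sigma)
}

#' Generate noisy projection segments with known transforms
#'
#' Emulates segment extraction along a filament: overlapping boxes are
#' sampled every `spacing` Angstrom along the axis, each projected
#' (line integral over the slab thickness), rotated in-plane by a random
#' psi, shifted by a random sub-box offset, and corrupted with additive
#' white Gaussian noise scaled to the noiseless signal RMS. The generating
#' transform of every segment is recorded, so alignment and compositing can
#' be validated against ground truth.
#'
#' @param model a `filament_model` (straight, along z).
#' @param imaging an [imaging_params()].
#' @param n_segments number of segments (>= 1).
#' @param spacing distance between segment centers along the axis, Angstrom.
#' @param psi_range range (degrees) of the uniform random in-plane rotation.
#' @param shift_max maximum absolute random shift, pixels.
#' @return Object of class `segment_stack`: `images` (box x box x n array),
#'   `records` (data.frame segment_id, filament_id, psi_deg, dx_px, dy_px,
#'   arc_A, class_id, seed), `imaging`, and `truth` (the model).
#' @export
project_segments <- function(model, imaging = imaging_params(),
                             n_segments = 100L, spacing = 42.5,
                             psi_range = c(-180, 180), shift_max = 4) {
  stopifnot(inherits(model, "lattice_model"))
  if (spacing <= 0) stop("'spacing' must be positive")
  if (n_segments < 1L) stop("'n_segments' must be >= 1")
  box <- imaging$box
  px <- imaging$pixel_size
  zr <- range(model$beads$z)
  margin <- box * px / 2 + 5 * model$geometry$bead_sigma
  z0 <- zr[1] + margin
  z1 <- zr[2] - margin
  need <- (n_segments - 1L) * spacing
  if (z1 - z0 < need)
    stop(sprintf(paste0("model too short: %d segments every %g A need ",
                        "%.0f A of filament inside margins, have %.0f A"),
                 n_segments, spacing, need, max(0, z1 - z0)))
  centers <- z0 + (seq_len(n_segments) - 1L) * spacing
  set.seed(imaging$seed)
  psi <- stats::runif(n_segments, psi_range[1], psi_range[2])
  dx <- stats::runif(n_segments, -shift_max, shift_max)
  dy <- stats::runif(n_segments, -shift_max, shift_max)
  images <- array(0, c(box, box, n_segments))
  half_diag <- box * px / sqrt(2) + 5 * model$geometry$bead_sigma
  for (i in seq_len(n_segments)) {
    sel <- abs(model$beads$z - centers[i]) <= half_diag
    sub <- model
    sub$beads <- model$beads[sel, ]
    img <- project_model(sub, box, box, px, center_z = centers[i],
                         thickness = imaging$projection_thickness,
                         psi = psi[i], dx = dx[i], dy = dy[i])
    if (imaging$noise_sigma > 0) {
      rms <- sqrt(mean(img^2))
      img <- img + stats::rnorm(box * box, 0, imaging$noise_sigma * rms)
    }
    images[, , i] <- img
  }
  records <- data.frame(segment_id = seq_len(n_segments), filament_id = 1L,
                        psi_deg = psi, dx_px = dx, dy_px = dy,
                        arc_A = centers, class_id = NA_integer_,
                        seed = imaging$seed)
  s <- list(images = images, records = records, imaging = imaging,
            truth = model)
  class(s) <- "segment_stack"
  s
}

#' @export
print.segment_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Segment stack: %d images %d x %d px (%.3g A/px)\n",
              d[3], d[1], d[2], x$imaging$pixel_size))
  invisible(x)
}

#' Noiseless ground-truth image of one segment
#'
#' Regenerates the projection of segment `i` from the stack's model and its
#' recorded transform, without noise. Used to validate alignment,
#' compositing and the stack's transform bookkeeping.
#'
#' @param stack a `segment_stack` with `truth`.
#' @param i segment index.
#' @param identity if `TRUE`, the canonical (unrotated, unshifted) segment
#'   projection is returned instead.
#' @return Matrix of the noiseless segment image.
#' @export
segment_truth_projection <- function(stack, i, identity = FALSE) {
  r <- stack$records[i, ]
  box <- stack$imaging$box
  project_model(stack$truth, box, box, stack$imaging$pixel_size,
                center_z = r$arc_A,
                thickness = stack$imaging$projection_thickness,
                psi = if (identity) 0 else r$psi_deg,
                dx = if (identity) 0 else r$dx_px,
                dy = if (identity) 0 else r$dy_px)
}

#' Render a bead model as a 3D density map
#'
#' Gaussian-blob rendering: every bead deposits its mass as an isotropic 3D
#' Gaussian (sd = the geometry's `bead_sigma`), normalized so the
#' integrated density equals the total bead mass. The model must fit in
#' the box.
#'
#' @param model a `filament_model`/`lattice_model`.
#' @param voxel_size voxel edge, Angstrom.
#' @param box integer vector of 3 (or 1, cubed) voxel counts; default
#'   chosen to fit the model with a 25 A margin.
#' @return A [density_map()].
#' @export
render_density_map <- function(model, voxel_size = 3.44, box = NULL) {
  stopifnot(inherits(model, "lattice_model"))
  b <- model$beads
  margin <- 25
  if (is.null(box)) {
    ext <- apply(as.matrix(b[, c("x", "y", "z")]), 2, function(v)
      diff(range(v)))
    box <- as.integer(ceiling((ext + 2 * margin) / voxel_size))
    box <- box + box %% 2L
  }
  if (length(box) == 1L) box <- rep(as.integer(box), 3L)
  if (nrow(b) == 0L)
    return(density_map(array(0, box), voxel_size))
  ctr <- vapply(b[, c("x", "y", "z")], function(v) mean(range(v)), numeric(1))
  half <- box * voxel_size / 2
  ext_ok <- vapply(seq_len(3L), function(i) {
    v <- b[[c("x", "y", "z")[i]]] - ctr[i]
    all(abs(v) + 4 * model$geometry$bead_sigma <= half[i])
  }, logical(1))
  if (!all(ext_ok))
    stop("model exceeds the requested box; enlarge 'box'")
  offs <- vapply(seq_len(3L), function(i)
    img_center(box[i]) - ctr[i] / voxel_size, numeric(1))
  grid <- splat_gaussians_3d(b$x, b$y, b$z, b$mass, box, voxel_size, offs,
                             sigma = model$geometry$bead_sigma)
  m <- density_map(grid, voxel_size,
                   origin = -(offs - 1) * voxel_size)
  m$center_offset <- offs
  m
}

#' Corrupt a density map with a tomographic missing wedge
#'
#' Single-axis tomography with tilts restricted to `tilt_range` about the x
#' axis only samples Fourier planes whose (ky, kz) direction satisfies
#' atan(kz/ky) within the tilt range; all other coefficients are zeroed.
#' The full range (-90, 90) leaves the map unchanged, and the operation is
#' idempotent.
#'
#' @param map a [density_map()].
#' @param tilt_range `(tilt_min, tilt_max)` in degrees, within `[-90, 90]`.
#' @return The corrupted [density_map()], flagged with the wedge.
#' @export
apply_missing_wedge <- function(map, tilt_range = c(-60, 60)) {
  stopifnot(inherits(map, "density_map"))
  if (length(tilt_range) != 2L || tilt_range[1] >= tilt_range[2] ||
      tilt_range[1] < -90 || tilt_range[2] > 90)
    stop("'tilt_range' must be (tilt_min, tilt_max) within [-90, 90]")
  d <- dim(map$grid)
  F <- stats::fft(map$grid)
  ky <- fft_freqs_unshifted(d[2])
  kz <- fft_freqs_unshifted(d[3])
  KY <- matrix(rep(ky, times = d[3]), d[2], d[3])
  KZ <- matrix(rep(kz, each = d[2]), d[2], d[3])
  ang <- atan2(KZ, KY) * 180 / pi
  ang <- ifelse(ang > 90, ang - 180, ifelse(ang <= -90, ang + 180, ang))
  keep <- (ang >= tilt_range[1] & ang <= tilt_range[2]) | (KY == 0 & KZ == 0)
  mask3 <- array(rep(as.numeric(keep), each = d[1]), d)
  out <- Re(stats::fft(F * mask3, inverse = TRUE)) / prod(d)
  density_map(out, map$voxel_size, map$origin, wedge = tilt_range)
}

# DFT frequencies in natural (unshifted) order, cycles/sample
fft_freqs_unshifted <- function(n) {
  f <- c(seq(0L, floor(n / 2)), seq(-ceiling(n / 2) + 1L, -1L)) / n
  f[seq_len(n)]
}

#' Bend a straight filament model along a 3D path
#'
#' Re-maps the beads of a straight model (axis = z) onto a smooth
#' centerline by transporting a rigid frame along the arc-length
#' parameterized spline through the control points (rotation-minimizing
#' parallel transport). Arc length is preserved; the path must be long
#' enough for the model and must not bend tighter than twice the filament
#' radius.
#'
#' @param model a straight `filament_model`.
#' @param path_control_points m x 3 matrix of centerline control points,
#'   Angstrom.
#' @return The bent model, with `path` recording the control points.
#' @export
bend_path <- function(model, path_control_points) {
  stopifnot(inherits(model, "lattice_model"))
  P <- as.matrix(path_control_points)
  if (ncol(P) != 3L || nrow(P) < 2L)
    stop("'path_control_points' must be an m x 3 matrix with m >= 2")
  b <- model$beads
  zmin <- min(b$z)
  need <- diff(range(b$z))
  fr <- path_frames(P, n_fine = max(1000L, 20L * nrow(P)))
  if (fr$arc[length(fr$arc)] < need)
    stop(sprintf("path too short: arc length %.0f A < model extent %.0f A",
                 fr$arc[length(fr$arc)], need))
  rmin <- 2 * (if (!is.null(model$radius)) model$radius
               else model$geometry$filament_radius)
  if (max(fr$curvature) > 1 / rmin)
    stop(sprintf("path curvature radius %.0f A below the allowed %.0f A",
                 1 / max(fr$curvature), rmin))
  s <- b$z - zmin
  Ci <- apply(fr$C, 2, function(col) stats::approx(fr$arc, col, s)$y)
  Ni <- apply(fr$N, 2, function(col) stats::approx(fr$arc, col, s)$y)
  Bi <- apply(fr$B, 2, function(col) stats::approx(fr$arc, col, s)$y)
  nrm <- function(M) M / sqrt(rowSums(M^2))
  Ni <- nrm(Ni); Bi <- nrm(Bi)
  new_xyz <- Ci + Ni * b$x + Bi * b$y
  model$beads[, c("x", "y", "z")] <- new_xyz
  model$path <- P
  model$chain_spans <- NULL  # spans are defined for straight models only
  model
}

# Spline the control points, reparameterize by arc length and parallel
# transport an orthonormal frame (C, T, N, B) along it.
path_frames <- function(P, n_fine = 2000L) {
  t0 <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  sp <- lapply(1:3, function(j) stats::splinefun(t0, P[, j], method = "natural"))
  tt <- seq(0, t0[length(t0)], length.out = n_fine)
  C <- sapply(sp, function(f) f(tt))
  dC <- sapply(sp, function(f) f(tt, deriv = 1))
  d2C <- sapply(sp, function(f) f(tt, deriv = 2))
  speed <- sqrt(rowSums(dC^2))
  arc <- c(0, cumsum((speed[-1] + speed[-n_fine]) / 2 * diff(tt)))
  Tn <- dC / speed
  # curvature of a space curve: |r' x r''| / |r'|^3
  cx <- dC[, 2] * d2C[, 3] - dC[, 3] * d2C[, 2]
  cy <- dC[, 3] * d2C[, 1] - dC[, 1] * d2C[, 3]
  cz <- dC[, 1] * d2C[, 2] - dC[, 2] * d2C[, 1]
  curvature <- sqrt(cx^2 + cy^2 + cz^2) / speed^3
  N <- matrix(0, n_fine, 3L)
  ref <- if (abs(Tn[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n0 <- ref - sum(ref * Tn[1, ]) * Tn[1, ]
  N[1, ] <- n0 / sqrt(sum(n0^2))
  for (i in 2:n_fine) {
    v <- N[i - 1L, ] - sum(N[i - 1L, ] * Tn[i, ]) * Tn[i, ]
    N[i, ] <- v / sqrt(sum(v^2))
  }
  B <- cbind(Tn[, 2] * N[, 3] - Tn[, 3] * N[, 2],
             Tn[, 3] * N[, 1] - Tn[, 1] * N[, 3],
             Tn[, 1] * N[, 2] - Tn[, 2] * N[, 1])
  list(C = C, T = Tn, N = N, B = B, arc = arc, curvature = curvature)
}

#' Re-orient a straight filament model onto another grid axis
#'
#' Rigidly rotates the model so its axis (built along z) lies along the
#' requested axis; used to place filaments perpendicular to the tilt axis
#' so their cross-sections fall into missing-wedge-affected planes.
#'
#' @param model a `filament_model`.
#' @param axis `"z"` (no-op), `"y"` or `"x"`.
#' @return The rotated model.
#' @export
orient_filament <- function(model, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  b <- model$beads
  if (axis == "y") {
    tmp <- b$y; model$beads$y <- b$z; model$beads$z <- -tmp
  } else if (axis == "x") {
    tmp <- b$x; model$beads$x <- b$z; model$beads$z <- -tmp
  }
  model$axis <- axis
  model
}

#' Wall asymmetry of a filament projection
#'
#' Relative imbalance of the integrated intensity between the two halves
#' of the projection on either side of the filament axis,
#' `|left - right| / (left + right)`. An even protofibril count places
#' protofibrils in diametrically opposed pairs, balancing the two walls;
#' an odd count makes one side of the filament boundary appear more
#' pronounced in projection.
#'
#' @param img projection image (lateral x axial), filament axis vertical
#'   and centered.
#' @return Scalar asymmetry (0 = balanced walls).
#' @export
wall_asymmetry <- function(img) {
  prof <- rowSums(img)
  c0 <- img_center(nrow(img))
  left <- sum(prof[seq_len(c0 - 1L)])
  right <- sum(prof[(c0 + 1L):length(prof)])
  abs(left - right) / max(left + right, 1e-300)
}

#' Write a segment stack to disk
#'
#' Images as an MRC stack, transform records as CSV with columns
#' segment_id, filament_id, psi_deg, dx_px, dy_px, arc_A, class_id, seed.
#'
#' @param stack a `segment_stack`.
#' @param prefix output path prefix (writes `<prefix>.mrcs` and
#'   `<prefix>_records.csv`).
#' @return Character vector of the files written, invisibly.
#' @export
write_segment_stack <- function(stack, prefix) {
  f1 <- paste0(prefix, ".mrcs")
  f2 <- paste0(prefix, "_records.csv")
  write_mrc(stack$images, f1, voxel_size = stack$imaging$pixel_size,
            is_stack = TRUE)
  utils::write.csv(stack$records, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Read a segment stack written by [write_segment_stack()]
#'
#' @param prefix path prefix used when writing.
#' @return A `segment_stack` (without ground-truth model).
#' @export
read_segment_stack <- function(prefix) {
  m <- read_mrc(paste0(prefix, ".mrcs"))
  rec <- utils::read.csv(paste0(prefix, "_records.csv"))
  if (nrow(rec) != dim(m$grid)[3])
    stop("record count does not match image count")
  s <- list(images = m$grid,
            records = rec,
            imaging = imaging_params(pixel_size = m$voxel_size,
                                     box = dim(m$grid)[1],
                                     seed = rec$seed[1]),
            truth = NULL)
  class(s) <- "segment_stack"
  s
}
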