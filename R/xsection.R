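# Transverse cross-section analysis: slab extraction from 3D maps,
# fixed-alignment averaging, and protofibril counting from the angular
# intensity profile over an annulus.

#' Extract transverse cross-sections from a density map
#'
#' Integrates slabs of the given thickness perpendicular to the filament
#' axis and returns square images centered on the axis. The filament is
#' assumed parallel to one of the grid axes (`axis`); its in-plane center
#' is taken from `axis_points` when supplied, otherwise from the intensity
#' centroid of the map. Sections whose window would leave the map are
#' skipped with a warning.
#'
#' @param map a [density_map()].
#' @param axis grid axis the filament runs along: `"z"` (default), `"y"`
#'   or `"x"`.
#' @param axis_points optional matrix of centerline samples (Angstrom, map
#'   frame) used for the in-plane center.
#' @param thickness slab thickness, Angstrom (default 8.84).
#' @param size_A section edge length, Angstrom (default 350, i.e. 35 nm).
#' @param positions optional axial positions (Angstrom along the axis,
#'   voxel-index scale starting at 0) of the requested sections; default:
#'   all non-overlapping slabs.
#' @return Object of class `xsection_stack`: `sections` (s x s x n),
#'   `thickness`, `pixel_size`, `source_wedge`, `positions_A`,
#'   `n_skipped`.
#' @export
extract_cross_sections <- function(map, axis = c("z", "y", "x"),
                                   axis_points = NULL, thickness = 8.84,
                                   size_A = 350, positions = NULL) {
  stopifnot(inherits(map, "density_map"))
  axis <- match.arg(axis)
  if (thickness <= 0) stop("'thickness' must be positive")
  g <- map$grid
  perm <- switch(axis, z = c(1L, 2L, 3L), y = c(1L, 3L, 2L),
                 x = c(3L, 2L, 1L))
  g <- aperm(g, perm)
  d <- dim(g)
  vox <- map$voxel_size
  s_px <- round(size_A / vox)
  s_px <- s_px + s_px %% 2L
  n_slab <- max(1L, round(thickness / vox))
  if (is.null(positions)) {
    starts <- seq(1L, d[3] - n_slab + 1L, by = n_slab)
  } else {
    starts <- round(positions / vox) + 1L
  }
  # in-plane center
  if (!is.null(axis_points)) {
    ap <- as.matrix(axis_points)
    ap3 <- ap[, perm, drop = FALSE]
    cx <- mean(ap3[, 1]) / vox - map$origin[perm[1]] / vox + 1
    cy <- mean(ap3[, 2]) / vox - map$origin[perm[2]] / vox + 1
  } else {
    w <- pmax(g, 0)
    tot <- sum(w)
    if (tot == 0) { cx <- d[1] / 2; cy <- d[2] / 2 } else {
      cx <- sum(slice_sums(w, 1L) * seq_len(d[1])) / tot
      cy <- sum(slice_sums(w, 2L) * seq_len(d[2])) / tot
    }
  }
  half <- s_px / 2
  ix <- round(cx) + seq(-half + 1L, half)
  iy <- round(cy) + seq(-half + 1L, half)
  sections <- list()
  pos <- numeric(0)
  skipped <- 0L
  for (s0 in starts) {
    s1 <- s0 + n_slab - 1L
    if (s0 < 1L || s1 > d[3] || min(ix) < 1L || max(ix) > d[1] ||
        min(iy) < 1L || max(iy) > d[2]) {
      skipped <- skipped + 1L
      next
    }
    slab <- g[ix, iy, s0:s1, drop = FALSE]
    sections[[length(sections) + 1L]] <- apply(slab, c(1L, 2L), sum) * vox
    pos <- c(pos, (s0 - 1L + n_slab / 2) * vox)
  }
  if (skipped > 0L)
    warning(skipped, " section(s) skipped: window outside the map")
  arr <- if (length(sections))
    array(unlist(sections), c(s_px, s_px, length(sections))) else
      array(0, c(s_px, s_px, 0L))
  x <- list(sections = arr, thickness = thickness, pixel_size = vox,
            source_wedge = map$wedge, positions_A = pos,
            n_skipped = skipped, alignment = NULL)
  class(x) <- "xsection_stack"
  x
}

slice_sums <- function(a, margin) apply(a, margin, sum)

#' @export
print.xsection_stack <- function(x, ...) {
  d <- dim(x$sections)
  cat(sprintf(
    "Cross-section stack: %d sections %d x %d px, %.3g A thick%s\n",
    d[3], d[1], d[2], x$thickness,
    if (is.null(x$source_wedge)) "" else " (wedge-corrupted source)"))
  invisible(x)
}

#' Average cross-sections under fixed alignment
#'
#' Rotates each section by its supplied in-plane angle (no alignment
#' search: the transforms are given, e.g. minus the helical twist
#' accumulated at the section's axial position) and averages. With the
#' correct de-rotation the protofibril pattern adds coherently; with
#' identity transforms on rotationally scrambled sections it smears into
#' an annulus.
#'
#' @param stack an `xsection_stack` (or 3D array).
#' @param rotations_deg one rotation per section, degrees.
#' @return The average image (matrix).
#' @export
average_fixed_alignment <- function(stack, rotations_deg) {
  arr <- if (inherits(stack, "xsection_stack")) stack$sections else stack
  n <- dim(arr)[3]
  if (length(rotations_deg) != n)
    stop("need exactly one rotation per section (", n, "), got ",
         length(rotations_deg))
  if (n == 0L) stop("empty section stack")
  acc <- matrix(0, dim(arr)[1], dim(arr)[2])
  for (i in seq_len(n)) {
    im <- arr[, , i]
    if (rotations_deg[i] != 0) im <- transform_image(im, rotations_deg[i])
    acc <- acc + im
  }
  acc / n
}

#' Angular intensity profile over an annulus
#'
#' Mean intensity in angular bins over the annulus
#' `annulus_radius +/- annulus_width/2`, sampled bilinearly.
#'
#' @param image square cross-section image.
#' @param pixel_size Angstrom per pixel.
#' @param annulus_radius annulus center radius, Angstrom (default 38, the
#'   protofibril center radius).
#' @param annulus_width radial width, Angstrom (default 20).
#' @param angular_step bin width, degrees (default 2).
#' @return Numeric vector of bin means; names give bin-center angles.
#' @export
annular_profile <- function(image, pixel_size, annulus_radius = 38,
                            annulus_width = 20, angular_step = 2) {
  r0 <- annulus_radius - annulus_width / 2
  r1 <- annulus_radius + annulus_width / 2
  if (r1 / pixel_size > min(dim(image)) / 2 - 1)
    stop("annulus extends outside the image")
  if (r0 < 0) stop("annulus width exceeds twice the radius")
  angles <- seq(0, 360 - angular_step, by = angular_step)
  radii <- seq(r0, r1, by = min(pixel_size, annulus_width) / 2)
  cx <- img_center(nrow(image)); cy <- img_center(ncol(image))
  prof <- vapply(angles + angular_step / 2, function(a) {
    th <- a * pi / 180
    xs <- cx + radii * cos(th) / pixel_size
    ys <- cy + radii * sin(th) / pixel_size
    mean(bilinear_sample(image, xs, ys))
  }, numeric(1))
  names(prof) <- angles + angular_step / 2
  prof
}

#' Count protofibrils in a cross-section image
#'
#' Integrates intensity over the annulus as a function of polar angle and
#' counts peaks of the circularly continuous profile with topographic
#' prominence above `prominence_frac` of the profile's max-minus-median.
#'
#' @inheritParams annular_profile
#' @param prominence_frac prominence threshold fraction (default 0.2).
#' @param smooth half-width of the circular moving-average smoothing, in
#'   bins (default 1).
#' @return List: `count`, `profile`, `peak_angles_deg`, `contrast`
#'   (peak-to-mean ratio of the profile).
#' @export
count_protofibrils <- function(image, pixel_size, annulus_radius = 38,
                               annulus_width = 20, angular_step = 2,
                               prominence_frac = 0.2, smooth = 1L) {
  prof <- annular_profile(image, pixel_size, annulus_radius, annulus_width,
                          angular_step)
  n <- length(prof)
  if (smooth > 0L) {
    k <- 2L * smooth + 1L
    ext <- c(prof[(n - smooth + 1L):n], prof, prof[1:smooth])
    prof <- stats::filter(ext, rep(1 / k, k))[(smooth + 1L):(smooth + n)]
    prof <- as.numeric(prof)
    names(prof) <- names(annular_profile(image, pixel_size, annulus_radius,
                                         annulus_width, angular_step))
  }
  thr <- prominence_frac * (max(prof) - stats::median(prof))
  if (max(prof) - min(prof) < 1e-12 * max(abs(prof), 1)) {
    return(list(count = 0L, profile = prof,
                peak_angles_deg = numeric(0),
                contrast = if (mean(prof) != 0) max(prof) / mean(prof) else 0))
  }
  # circular peak finding: triplicate the profile, keep the middle copy
  tri <- c(prof, prof, prof)
  pk <- find_peaks_1d(tri, min_prominence = max(thr, 1e-12))
  mid <- pk$index > n & pk$index <= 2L * n
  idx <- pk$index[mid] - n
  angs <- as.numeric(names(prof))[idx]
  list(count = length(idx), profile = prof, peak_angles_deg = angs,
       contrast = if (mean(prof) != 0) max(prof) / mean(prof) else 0)
}

#' Angular periodicity of an annular profile
#'
#' Normalized circular autocorrelation of the annular intensity profile at
#' a given angular lag. For a five-protofibril cross-section the profile
#' repeats every 72 degrees, giving values near 1 under full Fourier
#' sampling; missing-wedge corruption degrades the periodicity. This is
#' the package's quantitative measure of angular contrast of the
#' protofibril pattern.
#'
#' @param profile annular profile from [annular_profile()] (or the
#'   `profile` field of [count_protofibrils()]).
#' @param period_deg angular lag, degrees (default 72 = 360/5).
#' @param angular_step bin width of the profile, degrees (default 2).
#' @return Correlation in `[-1, 1]`.
#' @export
angular_periodicity <- function(profile, period_deg = 72, angular_step = 2) {
  k <- round(period_deg / angular_step)
  p <- as.numeric(profile) - mean(profile)
  if (sum(p^2) == 0) return(0)
  sum(p * c(p[-seq_len(k)], p[seq_len(k)])) / sum(p^2)
}

#' Write cross-section results to disk
#'
#' Sections as an MRC stack; counts and angular profiles as CSV.
#'
#' @param stack an `xsection_stack`.
#' @param counts optional list of [count_protofibrils()] results, one per
#'   section.
#' @param prefix output path prefix.
#' @return Files written, invisibly.
#' @export
write_xsection_results <- function(stack, counts = NULL, prefix) {
  f1 <- paste0(prefix, "_sections.mrcs")
  write_mrc(stack$sections, f1, voxel_size = stack$pixel_size,
            is_stack = TRUE)
  files <- f1
  if (!is.null(counts)) {
    f2 <- paste0(prefix, "_counts.csv")
    utils::write.csv(
      data.frame(section = seq_along(counts),
                 count = vapply(counts, `[[`, integer(1), "count"),
                 contrast = vapply(counts, `[[`, numeric(1), "contrast")),
      f2, row.names = FALSE)
    f3 <- paste0(prefix, "_profiles.csv")
    profs <- do.call(cbind, lapply(counts, `[[`, "profile"))
    utils::write.csv(data.frame(angle_deg = as.numeric(rownames(profs)),
                                profs), f3, row.names = FALSE)
    files <- c(files, f2, f3)
  }
  invisible(files)
}
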