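# Layer-line machinery: averaged power spectra of aligned segments,
# autocorrelation repeat measurement, zero-order-Bessel meridional
# scanning, layer-line picking and the P = n * h least-squares indexing.
#
# A power spectrum is stored fftshifted as power[kx, ky] with the meridian
# (filament axis direction) along ky at kx = center. Axial positions are in
# 1/Angstrom; the reciprocal pixel is 1/(n * pixel_size) per axis.

#' Averaged power spectrum of a segment stack
#'
#' Rotates each segment to the vertical-axis frame using its recorded
#' in-plane angle (translations do not affect the power spectrum) and
#' averages the per-image power |FFT|^2 / Npix. The result is Friedel
#' symmetric with a calibrated reciprocal pixel.
#'
#' @param stack a `segment_stack`, or a 3D array of pre-aligned images (in
#'   which case `pixel_size` must be given and no rotation is applied).
#' @param pixel_size Angstrom per pixel (taken from the stack if omitted).
#' @param apply_records rotate segments by -psi from the records before
#'   transforming (default `TRUE` for stacks).
#' @return Object of class `power_spectrum`: `power` (fftshifted,
#'   `nx x ny`), `reciprocal_pixel` (length 2, 1/A per pixel along kx, ky),
#'   `pixel_size`, `meridian_axis` (= 2), `n_images`.
#' @export
average_power_spectrum <- function(stack, pixel_size = NULL,
                                   apply_records = TRUE) {
  if (inherits(stack, "segment_stack")) {
    imgs <- stack$images
    pixel_size <- stack$imaging$pixel_size
    psi <- if (apply_records) stack$records$psi_deg else
      rep(0, dim(imgs)[3])
  } else {
    if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
    imgs <- stack
    if (is.null(pixel_size)) stop("'pixel_size' required for a bare array")
    psi <- rep(0, dim(imgs)[3])
  }
  n <- dim(imgs)[3]
  if (n < 1L) stop("empty image stack")
  nx <- dim(imgs)[1]; ny <- dim(imgs)[2]
  acc <- matrix(0, nx, ny)
  for (i in seq_len(n)) {
    im <- imgs[, , i]
    if (psi[i] != 0) im <- transform_image(im, -psi[i])
    acc <- acc + Mod(stats::fft(im))^2 / (nx * ny)
  }
  ps <- list(power = fftshift2(acc / n),
             reciprocal_pixel = c(1 / (nx * pixel_size),
                                  1 / (ny * pixel_size)),
             pixel_size = pixel_size, meridian_axis = 2L,
             n_images = n, dim = c(nx, ny))
  class(ps) <- "power_spectrum"
  ps
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "Power spectrum %d x %d (avg of %d), reciprocal pixel %.3g 1/A axial\n",
    x$dim[1], x$dim[2], x$n_images, x$reciprocal_pixel[2]))
  invisible(x)
}

# axial reciprocal coordinate (1/A) of every ky row, fftshifted order
ps_axial_coords <- function(ps) {
  fft_freqs(ps$dim[2]) / ps$pixel_size
}

ps_lateral_coords <- function(ps) {
  fft_freqs(ps$dim[1]) / ps$pixel_size
}

#' Measure an axial repeat distance by autocorrelation
#'
#' Computes the axial (zero lateral lag) profile of the unbiased,
#' variance-normalized autocorrelation of each image and locates the
#' repeat: the first local maximum whose height reaches `accept_frac` of
#' the strongest local maximum (so the fundamental repeat is preferred
#' over its multiples). Images with no local maximum above `threshold`
#' are flagged aperiodic.
#'
#' @param images matrix, 3D array or list of images (lateral x axial).
#' @param pixel_size Angstrom per pixel.
#' @param min_lag_A ignore lags shorter than this (default 20 A).
#' @param max_lag_frac search lags up to this fraction of the image height
#'   (default 0.45).
#' @param threshold minimum normalized correlation of an acceptable peak
#'   (default 0.2).
#' @param accept_frac fraction of the best peak height at which the first
#'   (shortest-lag) peak is accepted as the fundamental (default 0.9).
#' @return List: `repeat_A` (mean over periodic images, `NA` if none),
#'   `sd_A`, `per_image` (per-image repeats), `aperiodic` (logical).
#' @export
autocorrelation_repeat <- function(images, pixel_size, min_lag_A = 20,
                                   max_lag_frac = 0.45, threshold = 0.2,
                                   accept_frac = 0.9) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  reps <- vapply(images, function(im) {
    nx <- nrow(im); ny <- ncol(im)
    im <- im - mean(im)
    pad <- matrix(0, nx, 2L * ny)
    pad[, seq_len(ny)] <- im
    ac2 <- Re(stats::fft(Mod(stats::fft(pad))^2, inverse = TRUE)) /
      (nx * 2 * ny)
    prof <- ac2[1L, seq_len(ny)]            # zero lateral lag, axial lags
    prof <- prof / (ny - (seq_len(ny) - 1L))  # unbiased
    prof <- prof / prof[1L]
    lags <- (seq_len(ny) - 1L)
    lo <- max(2L, ceiling(min_lag_A / pixel_size))
    hi <- floor(ny * max_lag_frac)
    if (hi <= lo + 1L) return(NA_real_)
    seg <- prof[(lo):(hi)]
    pk <- find_peaks_1d(seg)
    pk <- pk[pk$height >= threshold, , drop = FALSE]
    if (nrow(pk) == 0L) return(NA_real_)
    best <- max(pk$height)
    first <- pk[which(pk$height >= accept_frac * best)[1L], ]
    i_abs <- first$index + lo - 1L
    frac <- parabolic_refine(prof, i_abs)
    (lags[i_abs] + frac) * pixel_size
  }, numeric(1))
  periodic <- !is.na(reps)
  list(repeat_A = if (any(periodic)) mean(reps[periodic]) else NA_real_,
       sd_A = if (sum(periodic) > 1L) stats::sd(reps[periodic]) else NA_real_,
       per_image = reps, aperiodic = !any(periodic))
}

#' Zero-order Bessel meridional template
#'
#' The expected lateral amplitude profile of a meridional reflection of a
#' helical filament of the given radius: J0(2 pi * radius * r), evaluated
#' at lateral reciprocal coordinates r (1/A). Its value is 1 at r = 0 and
#' its first zero falls at 2.4048 / (2 pi * radius), i.e. 1/143.7 A for a
#' 55 A filament radius.
#'
#' @param radius filament radius, Angstrom.
#' @param r_A_inv lateral reciprocal coordinates, 1/A.
#' @return Numeric vector of template values.
#' @export
bessel_meridional_template <- function(radius, r_A_inv) {
  besselJ(2 * pi * radius * abs(r_A_inv), 0)
}

#' Scan power-spectrum rows against a zero-order Bessel template
#'
#' Extracts 1-pixel-wide rows of the power spectrum at axial positions
#' inside `band` and cross-correlates each (Pearson, zero lag) with the
#' template J0(2 pi * radius * r) sampled on the row's lateral reciprocal
#' coordinates r. A row dominated by a meridional (Bessel order 0)
#' reflection matches the template's central maximum; off-meridional layer
#' lines (higher orders) dip at the meridian and score lower. The
#' best-scoring row, refined by 3-point parabolic interpolation, gives the
#' helical rise as 1/position. Rows whose amplitude falls below
#' `min_row_amplitude` of the strongest row in the band carry no layer-line
#' signal (spectral leakage between lines would otherwise win on shape
#' alone) and are not eligible as the best row. The best is flagged
#' unreliable when it does not stand out from the score profile (robust
#' 3-sigma criterion).
#'
#' @param ps a `power_spectrum`.
#' @param radius assumed filament radius, Angstrom (default 55).
#' @param band axial reciprocal interval searched, 1/A (default the
#'   1/69 - 1/30 band).
#' @param lateral_max_A_inv restrict the template comparison to lateral
#'   frequencies up to this value (default: the full row).
#' @param min_row_amplitude eligibility floor for the best row, as a
#'   fraction of the strongest row's RMS amplitude (default 0.2).
#' @return Object of class `meridional_scan`: `row_positions` (1/A),
#'   `scores`, `amplitudes` (row RMS), `radius`, `best` (1/A, refined),
#'   `rise_A` (= 1/best), `reliable`.
#' @export
scan_meridional_bessel <- function(ps, radius = 55, band = c(1 / 69, 1 / 30),
                                   lateral_max_A_inv = NULL,
                                   min_row_amplitude = 0.2) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (radius <= 0) stop("'radius' must be positive")
  band <- sort(band)
  ax <- ps_axial_coords(ps)
  nyq <- 1 / (2 * ps$pixel_size)
  if (band[2] > nyq + 1e-12)
    stop("band extends beyond the Nyquist frequency")
  rows <- which(ax >= band[1] & ax <= band[2])
  if (length(rows) < 1L)
    stop("no spectrum rows inside the requested band")
  lat <- ps_lateral_coords(ps)
  sel <- if (is.null(lateral_max_A_inv)) rep(TRUE, length(lat)) else
    abs(lat) <= lateral_max_A_inv
  template <- bessel_meridional_template(radius, lat[sel])
  amp <- vapply(rows, function(j) sqrt(mean(ps$power[sel, j])), numeric(1))
  scores <- vapply(rows, function(j) {
    row <- sqrt(ps$power[sel, j])
    if (stats::sd(row) == 0) return(0)
    stats::cor(row, template)
  }, numeric(1))
  eligible <- amp >= min_row_amplitude * max(amp)
  ib <- which(eligible)[which.max(scores[eligible])]
  frac <- if (ib > 1L && ib < length(rows)) parabolic_refine(scores, ib) else 0
  best <- ax[rows[ib]] + frac * ps$reciprocal_pixel[2]
  med <- stats::median(scores)
  madv <- stats::mad(scores)
  reliable <- length(scores) >= 3L && madv > 0 &&
    (scores[ib] - med) > 3 * madv
  sc <- list(row_positions = ax[rows], scores = scores, amplitudes = amp,
             radius = radius, best = best, rise_A = 1 / best,
             reliable = reliable, band = band)
  class(sc) <- "meridional_scan"
  sc
}

#' @export
print.meridional_scan <- function(x, ...) {
  cat(sprintf(
    "Meridional scan (J0, radius %g A): best row at %.5g 1/A -> rise %.4g A%s\n",
    x$radius, x$best, x$rise_A, if (x$reliable) "" else " (unreliable)"))
  invisible(x)
}

#' Pick layer lines from a power spectrum
#'
#' Integrates the spectrum amplitude laterally about the meridian, then
#' finds local maxima of the axial profile with topographic prominence of
#' at least `min_prominence` times the profile's max-min range.
#'
#' @param ps a `power_spectrum`.
#' @param band axial reciprocal search interval, 1/A.
#' @param min_prominence prominence threshold as a fraction of the profile
#'   range (1.0 keeps at most the global maximum).
#' @param lateral_window_A_inv half-width of the lateral integration
#'   window, 1/A (default 0.03, wide enough to catch low-order Bessel
#'   maxima for a ~40-55 A radius filament).
#' @return Object of class `layer_line_picks`: `positions` (1/A,
#'   increasing), `periods_A`, `heights`, `band`.
#' @export
pick_layer_lines <- function(ps, band = c(1 / 400, 1 / 25),
                             min_prominence = 0.1,
                             lateral_window_A_inv = 0.03) {
  stopifnot(inherits(ps, "power_spectrum"))
  band <- sort(band)
  ax <- ps_axial_coords(ps)
  nyq <- 1 / (2 * ps$pixel_size)
  if (band[2] > nyq + 1e-12)
    stop("band extends beyond the Nyquist frequency")
  lat <- ps_lateral_coords(ps)
  sel <- abs(lat) <= lateral_window_A_inv
  if (!any(sel)) sel[img_center(ps$dim[1]) + (-3:3)] <- TRUE
  profile <- colSums(sqrt(ps$power[sel, , drop = FALSE]))
  rows <- which(ax >= band[1] & ax <= band[2])
  if (length(rows) < 3L)
    return(structure(list(positions = numeric(0), periods_A = numeric(0),
                          heights = numeric(0), band = band),
                     class = "layer_line_picks"))
  seg <- profile[rows]
  rng <- diff(range(seg))
  pk <- find_peaks_1d(seg, min_prominence = min_prominence * max(rng, 1e-300))
  pos <- vapply(seq_len(nrow(pk)), function(i) {
    j <- pk$index[i]
    ax[rows[j]] + parabolic_refine(seg, j) * ps$reciprocal_pixel[2]
  }, numeric(1))
  o <- order(pos)
  structure(list(positions = pos[o], periods_A = 1 / pos[o],
                 heights = pk$height[o], band = band),
            class = "layer_line_picks")
}

#' @export
print.layer_line_picks <- function(x, ...) {
  cat(sprintf("%d layer line(s) in [%.4g, %.4g] 1/A\n", length(x$positions),
              x$band[1], x$band[2]))
  if (length(x$positions))
    print(data.frame(position_A_inv = x$positions, period_A = x$periods_A,
                     height = x$heights))
  invisible(x)
}

#' Index paired layer-line sequences by P = n * h
#'
#' Given a sequence of pitch-associated layer-line periods P_i and the
#' positionally paired sequence of rise-associated periods h_i, finds the
#' number of asymmetric units per pitch as the closed-form least-squares
#' minimizer of sum_i (P_i - n h_i)^2, i.e. n = sum(P h) / sum(h^2). The
#' estimator is scale-equivariant: rescaling both sequences leaves n
#' unchanged.
#'
#' @param pitch_sequence periods of the pitch-associated layer lines, A.
#' @param rise_sequence periods of the rise-associated layer lines, A,
#'   same length, paired in order.
#' @return List: `n`, `params` (a [helical_params()] built from n and the
#'   first rise period), `residuals_A` (P_i - n h_i).
#' @export
index_layer_lines <- function(pitch_sequence, rise_sequence) {
  P <- as.numeric(pitch_sequence)
  h <- as.numeric(rise_sequence)
  if (length(P) != length(h))
    stop("pitch and rise sequences must have equal length")
  if (length(P) < 1L) stop("need at least one layer-line pair")
  if (any(!is.finite(P)) || any(!is.finite(h)) || any(P <= 0) || any(h <= 0))
    stop("all layer-line periods must be positive")
  n <- sum(P * h) / sum(h^2)
  list(n = n, params = params_from_units(n, h[1]), residuals_A = P - n * h)
}

#' Write spectral results to disk
#'
#' The power spectrum as an MRC image, picks/scans as CSV
#' (position_A_inv, period_A, score) and the indexing summary as JSON
#' `{n, rise_A, twist_deg, pitch_A}`.
#'
#' @param ps a `power_spectrum` (or NULL).
#' @param scan a `meridional_scan` (or NULL).
#' @param picks a `layer_line_picks` (or NULL).
#' @param indexing result of [index_layer_lines()] (or NULL).
#' @param prefix output path prefix.
#' @return Files written, invisibly.
#' @export
write_spectral_results <- function(ps = NULL, scan = NULL, picks = NULL,
                                   indexing = NULL, prefix) {
  files <- character(0)
  if (!is.null(ps)) {
    f <- paste0(prefix, "_ps.mrc")
    write_mrc(ps$power, f, voxel_size = ps$reciprocal_pixel[2])
    files <- c(files, f)
  }
  if (!is.null(scan)) {
    f <- paste0(prefix, "_meridional.csv")
    utils::write.csv(data.frame(position_A_inv = scan$row_positions,
                                period_A = 1 / scan$row_positions,
                                score = scan$scores), f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(picks)) {
    f <- paste0(prefix, "_layerlines.csv")
    utils::write.csv(data.frame(position_A_inv = picks$positions,
                                period_A = picks$periods_A,
                                score = picks$heights), f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(indexing)) {
    f <- paste0(prefix, "_symmetry.json")
    jsonlite::write_json(list(n = indexing$n,
                              rise_A = indexing$params$rise,
                              twist_deg = indexing$params$twist,
                              pitch_A = indexing$params$pitch),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
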