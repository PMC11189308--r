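# Shared image arithmetic: FFT index helpers, bilinear resampling,
# Gaussian-bead splatting. Images are matrices img[ix, iy] with ix the
# lateral axis and iy the axial (filament) axis; the real-space origin sits
# at pixel c0 = floor(n/2) + 1 on each axis, matching the DC position of an
# fftshifted spectrum.

img_center <- function(n) floor(n / 2) + 1L

fftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- c(seq(img_center(nx) + 0L, nx), seq_len(img_center(nx) - 1L))
  sy <- c(seq(img_center(ny) + 0L, ny), seq_len(img_center(ny) - 1L))
  m[sx, sy, drop = FALSE]
}

# cycles per pixel for an n-point DFT, in fftshifted order
fft_freqs <- function(n) (seq_len(n) - img_center(n)) / n

#' Bilinear sampling of an image at arbitrary points
#'
#' Samples `img[ix, iy]` at continuous positions, returning 0 outside the
#' image. Used by every rotation/translation/resampling step in the package.
#'
#' @param img numeric matrix.
#' @param x,y continuous pixel coordinates (1-based, x along rows of `img`).
#' @return Numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  for (dx in 0:1) {
    for (dy in 0:1) {
      xi <- x0 + dx; yi <- y0 + dy
      w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
      ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny & w > 0
      if (any(ok))
        val[ok] <- val[ok] + w[ok] * img[cbind(xi[ok], yi[ok])]
    }
  }
  val
}

# In-plane transform convention used throughout: a record (psi, dx, dy)
# maps canonical coordinates p (about the image center, in px) to observed
# coordinates R(psi) p + (dx, dy). Angles in degrees, counterclockwise.

rot2 <- function(psi_deg) {
  th <- psi_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Apply an in-plane rotation + translation to an image
#'
#' Resamples `img` so that output = T(psi, dx, dy) applied to the input:
#' out(R(psi) p + d) = img(p), with p measured from the image center.
#' Bilinear interpolation; pixels mapped from outside the input are 0.
#'
#' @param img numeric matrix.
#' @param psi rotation in degrees (counterclockwise).
#' @param dx,dy translation in pixels (lateral, axial).
#' @return Transformed matrix, same size.
#' @export
transform_image <- function(img, psi, dx = 0, dy = 0) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- img_center(nx); cy <- img_center(ny)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  # gather: source = R(-psi) (p - d)
  px <- g$x - cx - dx; py <- g$y - cy - dy
  R <- rot2(-psi)
  sx <- R[1, 1] * px + R[1, 2] * py + cx
  sy <- R[2, 1] * px + R[2, 2] * py + cy
  matrix(bilinear_sample(img, sx, sy), nx, ny)
}

#' Invert an in-plane transform record
#'
#' Returns (psi', dx', dy') such that applying it undoes (psi, dx, dy).
#'
#' @param psi,dx,dy forward transform (degrees, px).
#' @return Named list with psi, dx, dy of the inverse.
#' @export
invert_transform <- function(psi, dx = 0, dy = 0) {
  R <- rot2(-psi)
  d <- -c(R[1, 1] * dx + R[1, 2] * dy, R[2, 1] * dx + R[2, 2] * dy)
  list(psi = -psi, dx = d[1], dy = d[2])
}

#' Normalized cross-correlation of two images
#'
#' Pearson correlation of the flattened pixel values; 1 for identical images
#' up to affine intensity scaling.
#'
#' @param a,b numeric matrices of equal size.
#' @return Scalar in `[-1, 1]`.
#' @export
image_ncc <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  av <- as.vector(a) - mean(a)
  bv <- as.vector(b) - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

# Splat point masses as isotropic 2D Gaussians (sd sigma, Angstrom) onto a
# nx x ny pixel grid. u, v are Angstrom coordinates; the grid origin (u=v=0)
# is at pixel (img_center(nx), img_center(ny)). Each bead deposits
# mass * px^2 * G2(sd sigma), truncated at 5 sigma, so the result matches
# the analytic Gaussian-blob projection to ~1e-6.
splat_gaussians_2d <- function(u, v, mass, nx, ny, pixel_size, sigma) {
  if (length(u) == 0L) return(matrix(0, nx, ny))
  cx <- img_center(nx); cy <- img_center(ny)
  pu <- u / pixel_size + cx
  pv <- v / pixel_size + cy
  r <- ceiling(5 * sigma / pixel_size)
  off <- -r:r
  n <- length(u)
  iu <- outer(round(pu), off, "+")          # n x w integer pixel columns
  iv <- outer(round(pv), off, "+")
  gu <- exp(-((iu - pu) * pixel_size)^2 / (2 * sigma^2))
  gv <- exp(-((iv - pv) * pixel_size)^2 / (2 * sigma^2))
  amp <- mass * pixel_size^2 / (2 * pi * sigma^2)
  w <- length(off)
  a <- rep(seq_len(w), times = w)
  b <- rep(seq_len(w), each = w)
  I <- iu[, a, drop = FALSE]
  J <- iv[, b, drop = FALSE]
  V <- (amp * gu)[, a, drop = FALSE] * gv[, b, drop = FALSE]
  ok <- I >= 1L & I <= nx & J >= 1L & J <= ny
  idx <- (J[ok] - 1L) * nx + I[ok]
  img <- numeric(nx * ny)
  acc <- rowsum(V[ok], idx)
  img[as.integer(rownames(acc))] <- acc
  matrix(img, nx, ny)
}

# 3D analogue; kernel normalized per bead so the integrated density equals
# sum(mass) exactly despite truncation (at 4 sigma).
splat_gaussians_3d <- function(x, y, z, mass, dims, voxel, center_offset,
                               sigma = 4) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  grid <- numeric(nx * ny * nz)
  if (length(x) == 0L) return(array(grid, dims))
  px <- x / voxel + center_offset[1]
  py <- y / voxel + center_offset[2]
  pz <- z / voxel + center_offset[3]
  r <- ceiling(4 * sigma / voxel)
  off <- -r:r
  w <- length(off)
  ix <- outer(round(px), off, "+"); gx <- exp(-((ix - px) * voxel)^2 / (2 * sigma^2))
  iy <- outer(round(py), off, "+"); gy <- exp(-((iy - py) * voxel)^2 / (2 * sigma^2))
  iz <- outer(round(pz), off, "+"); gz <- exp(-((iz - pz) * voxel)^2 / (2 * sigma^2))
  # normalize separably: sum_x gx * sum_y gy * sum_z gz = 1 per bead
  gx <- gx / rowSums(gx); gy <- gy / rowSums(gy); gz <- gz / rowSums(gz)
  a <- rep(seq_len(w), times = w * w)
  b <- rep(rep(seq_len(w), each = w), times = w)
  cc <- rep(seq_len(w), each = w * w)
  I <- ix[, a, drop = FALSE]; Jy <- iy[, b, drop = FALSE]; K <- iz[, cc, drop = FALSE]
  V <- (as.numeric(mass) * gx)[, a, drop = FALSE] *
    gy[, b, drop = FALSE] * gz[, cc, drop = FALSE]
  ok <- I >= 1L & I <= nx & Jy >= 1L & Jy <= ny & K >= 1L & K <= nz
  idx <- ((K[ok] - 1L) * ny + (Jy[ok] - 1L)) * nx + I[ok]
  acc <- rowsum(V[ok], idx)
  grid[as.integer(rownames(acc))] <- acc
  array(grid, dims)
}

# 1D local maxima with topographic prominence. Returns a data.frame with
# index, height, prominence. Endpoints are not peaks.
find_peaks_1d <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(), height = numeric(),
                                prominence = numeric()))
  is_pk <- which(diff(sign(diff(y))) < 0) + 1L
  # plateaus: keep strict-or-equal rises followed by falls
  if (length(is_pk) == 0L) return(data.frame(index = integer(),
                                             height = numeric(),
                                             prominence = numeric()))
  prom <- vapply(is_pk, function(i) {
    h <- y[i]
    lmin <- h
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      lmin <- min(lmin, y[j])
    }
    left_base <- if (j >= 1L && y[j] > h) lmin else min(y[1:i])
    rmin <- h
    j <- i
    while (j < n) {
      j <- j + 1L
      if (y[j] > h) break
      rmin <- min(rmin, y[j])
    }
    right_base <- if (j <= n && y[j] > h) rmin else min(y[i:n])
    h - max(left_base, right_base)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = is_pk[keep], height = y[is_pk[keep]],
             prominence = prom[keep])
}

# 3-point parabolic sub-sample refinement of a maximum at index i of y;
# returns fractional index shift in [-0.5, 0.5].
parabolic_refine <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (y[i - 1L] - y[i + 1L]) / den))
}
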