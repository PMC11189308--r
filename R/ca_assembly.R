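# Computational filament assembly: align segments against references,
# paste inverse-transformed class averages back into the filament frame,
# straighten bent filaments along a spline and box them to uniform length.

#' Align segments to reference images
#'
#' Assigns each segment the reference and in-plane transform (psi over a
#' discretized grid, integer shifts via FFT cross-correlation) maximizing
#' the normalized correlation, and stores them in the records. The model
#' is segment = translate(rotate(reference, psi), dx, dy), matching the
#' generator's convention.
#'
#' @param stack a `segment_stack`.
#' @param references list or 3D array of reference images (same box).
#' @param psi_step psi grid step, degrees (default 2).
#' @param shift_max maximum shift searched, pixels (default box/3).
#' @param score_threshold alignments scoring below this are flagged
#'   (class_id `NA`; default 0.2).
#' @return The stack with updated records (psi_deg, dx_px, dy_px,
#'   class_id, score).
#' @export
align_segments <- function(stack, references, psi_step = 2,
                           shift_max = NULL, score_threshold = 0.2) {
  if (is.array(references) && length(dim(references)) == 3L)
    references <- lapply(seq_len(dim(references)[3]),
                         function(i) references[, , i])
  if (is.matrix(references)) references <- list(references)
  if (length(references) == 0L) stop("empty reference set")
  box <- dim(stack$images)[1]
  if (is.null(shift_max)) shift_max <- floor(box / 3)
  psis <- seq(-180, 180 - psi_step, by = psi_step)
  # precompute rotated, normalized references in Fourier space
  refs_f <- lapply(references, function(ref) {
    ref <- (ref - mean(ref)) / stats::sd(ref)
    lapply(psis, function(p) {
      r <- transform_image(ref, p)
      list(fft = Conj(stats::fft(r)), norm = sqrt(sum(r^2)))
    })
  })
  shift_of_index <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  n <- dim(stack$images)[3]
  out <- stack$records
  out$score <- NA_real_
  for (i in seq_len(n)) {
    seg <- stack$images[, , i]
    seg <- seg - mean(seg)
    seg_norm <- sqrt(sum(seg^2))
    seg_f <- stats::fft(seg)
    best <- list(score = -Inf)
    for (ci in seq_along(refs_f)) {
      for (pi in seq_along(psis)) {
        rf <- refs_f[[ci]][[pi]]
        cc <- Re(stats::fft(seg_f * rf$fft, inverse = TRUE)) / length(seg)
        cc <- cc / (seg_norm * rf$norm)
        dxs <- shift_of_index(seq_len(box), box)
        ok <- abs(dxs) <= shift_max
        sub <- cc[ok, ok, drop = FALSE]
        m <- which.max(sub)
        sc <- sub[m]
        if (sc > best$score) {
          ii <- (m - 1L) %% nrow(sub) + 1L
          jj <- (m - 1L) %/% nrow(sub) + 1L
          best <- list(score = sc, psi = psis[pi], class = ci,
                       dx = dxs[ok][ii], dy = dxs[ok][jj])
        }
      }
    }
    out$psi_deg[i] <- best$psi
    out$dx_px[i] <- best$dx
    out$dy_px[i] <- best$dy
    out$class_id[i] <- if (best$score >= score_threshold) best$class else
      NA_integer_
    out$score[i] <- best$score
  }
  stack$records <- out
  stack
}

#' Composite a computationally assembled filament from class averages
#'
#' Inverts the recorded 2D transform of every segment, applies it to the
#' corresponding class-average image and pastes the result at the
#' segment's position along the filament axis, so the pasted images match
#' the filament frame; overlapping pastes are averaged with equal weight.
#' The support map counts contributing pastes per pixel; pixels with
#' support 0 carry no information and are excluded from statistics.
#'
#' @param class_averages list or 3D array of class-average images in the
#'   observed segment frame (the frame the records' transforms map to).
#' @param records transform records for the segments of one filament
#'   (columns psi_deg, dx_px, dy_px, arc_A, class_id; `NA` class ids are
#'   skipped).
#' @param pixel_size Angstrom per pixel.
#' @param width output width in pixels (default: the class-average box).
#' @return Object of class `ca_filament`: `image`, `support`, `length_A`,
#'   `pixel_size`, `arc_range_A`.
#' @export
composite_ca_filament <- function(class_averages, records, pixel_size,
                                  width = NULL) {
  if (is.array(class_averages) && length(dim(class_averages)) == 3L)
    class_averages <- lapply(seq_len(dim(class_averages)[3]),
                             function(i) class_averages[, , i])
  if (is.matrix(class_averages)) class_averages <- list(class_averages)
  if (nrow(records) == 0L) stop("no transform records supplied")
  if (length(unique(records$filament_id)) > 1L)
    stop("records must belong to a single filament")
  keep <- !is.na(records$class_id)
  if (!any(keep)) stop("no records with a valid class id")
  records <- records[keep, ]
  if (any(records$class_id < 1L |
          records$class_id > length(class_averages)))
    stop("class id outside the supplied class-average set")
  box <- nrow(class_averages[[1L]])
  if (is.null(width)) width <- box
  arc0 <- min(records$arc_A) - (box / 2) * pixel_size
  arc1 <- max(records$arc_A) + (box / 2) * pixel_size
  H <- ceiling((arc1 - arc0) / pixel_size)
  acc <- matrix(0, width, H)
  sup <- matrix(0, width, H)
  cw <- img_center(width); cb <- img_center(box)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ca <- class_averages[[r$class_id]]
    inv <- invert_transform(r$psi_deg, r$dx_px, r$dy_px)
    canonical <- transform_image(ca, inv$psi, inv$dx, inv$dy)
    mask <- transform_image(matrix(1, box, box), inv$psi, inv$dx, inv$dy)
    row0 <- round((r$arc_A - arc0) / pixel_size + 0.5) - cb
    for (j in seq_len(box)) {
      jj <- row0 + j
      if (jj < 1L || jj > H) next
      cols <- seq_len(box) - cb + cw
      okc <- cols >= 1L & cols <= width
      w <- mask[okc, j]
      acc[cols[okc], jj] <- acc[cols[okc], jj] + canonical[okc, j] * w
      sup[cols[okc], jj] <- sup[cols[okc], jj] + w
    }
  }
  img <- acc
  nz <- sup > 1e-6
  img[nz] <- acc[nz] / sup[nz]
  img[!nz] <- 0
  ca <- list(image = img, support = sup,
             length_A = diff(range(records$arc_A)) + box * pixel_size,
             pixel_size = pixel_size, arc_range_A = c(arc0, arc1))
  class(ca) <- "ca_filament"
  ca
}

#' @export
print.ca_filament <- function(x, ...) {
  cat(sprintf("Assembled filament image %d x %d px, length %.0f A\n",
              nrow(x$image), ncol(x$image), x$length_A))
  invisible(x)
}

#' Straighten a filament image along a spline path
#'
#' Resamples the image along the unit-speed (arc length) parameterization
#' of the spline through the control points: output row k is the intensity
#' profile perpendicular to the path at arc length k pixels, so the output
#' height equals the path arc length in pixels.
#'
#' @param image 2D image (lateral x axial).
#' @param path m x 2 matrix of centerline control points in pixel
#'   coordinates (x = lateral index, y = axial index), ordered along the
#'   filament; all must lie inside the image.
#' @param width output width, pixels.
#' @return `width` x `ceiling(arc length)` straightened image.
#' @export
straighten_filament <- function(image, path, width) {
  P <- as.matrix(path)
  if (ncol(P) != 2L || nrow(P) < 2L)
    stop("'path' must be an m x 2 matrix of pixel coordinates")
  bad <- which(P[, 1] < 1 | P[, 1] > nrow(image) |
                 P[, 2] < 1 | P[, 2] > ncol(image))
  if (length(bad))
    stop("path control point ", bad[1L], " at (",
         P[bad[1L], 1], ", ", P[bad[1L], 2], ") lies outside the image")
  t0 <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  fx <- stats::splinefun(t0, P[, 1], method = "natural")
  fy <- stats::splinefun(t0, P[, 2], method = "natural")
  tt <- seq(0, t0[length(t0)], length.out = max(2000L, 10L * nrow(P)))
  sp <- sqrt(fx(tt, deriv = 1)^2 + fy(tt, deriv = 1)^2)
  arc <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tt)))
  L <- floor(arc[length(arc)])
  s_of <- stats::approxfun(arc, tt)
  ts <- s_of(seq_len(L) - 1L)
  cxs <- fx(ts); cys <- fy(ts)
  tx <- fx(ts, deriv = 1); ty <- fy(ts, deriv = 1)
  nrm <- sqrt(tx^2 + ty^2)
  # unit normal chosen so a path running along +y keeps +x to the right,
  # making the straightened image an axis-aligned crop for vertical paths
  nxv <- ty / nrm; nyv <- -tx / nrm
  off <- seq_len(width) - img_center(width)
  X <- outer(nxv, off) + cxs
  Y <- outer(nyv, off) + cys
  vals <- bilinear_sample(image, as.vector(t(X)), as.vector(t(Y)))
  matrix(vals, width, L)
}

#' Box filament images to a uniform length
#'
#' Excludes filaments shorter than the target length and center-crops the
#' rest to exactly `length_A`, yielding a stack of identical dimensions.
#'
#' @param ca_filaments list of `ca_filament` objects (or bare images, in
#'   which case `pixel_size` must be given).
#' @param length_A target length, Angstrom.
#' @param pixel_size Angstrom per pixel for bare images.
#' @return List: `stack` (width x L x n array, possibly n = 0),
#'   `n_kept`, `n_excluded`, `length_px`.
#' @export
box_uniform_length <- function(ca_filaments, length_A, pixel_size = NULL) {
  if (length_A <= 0) stop("'length_A' must be positive")
  get_img <- function(f) if (inherits(f, "ca_filament")) f$image else f
  get_px <- function(f) if (inherits(f, "ca_filament")) f$pixel_size else
    pixel_size
  if (inherits(ca_filaments, "ca_filament") || is.matrix(ca_filaments))
    ca_filaments <- list(ca_filaments)
  px <- get_px(ca_filaments[[1L]])
  if (is.null(px)) stop("'pixel_size' required for bare images")
  Lpx <- round(length_A / px)
  imgs <- lapply(ca_filaments, get_img)
  keep <- vapply(imgs, function(im) ncol(im) >= Lpx, logical(1))
  kept <- imgs[keep]
  if (length(kept) == 0L)
    return(list(stack = array(0, c(0L, Lpx, 0L)), n_kept = 0L,
                n_excluded = sum(!keep), length_px = Lpx))
  w <- nrow(kept[[1L]])
  stack <- array(0, c(w, Lpx, length(kept)))
  for (i in seq_along(kept)) {
    im <- kept[[i]]
    start <- floor((ncol(im) - Lpx) / 2) + 1L
    stack[, , i] <- im[, start:(start + Lpx - 1L)]
  }
  list(stack = stack, n_kept = length(kept), n_excluded = sum(!keep),
       length_px = Lpx)
}
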