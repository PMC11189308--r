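# MRC2014 volume/stack I/O. Written here directly against the format
# definition (1024-byte header, mode-2 float32 data, little endian) because
# no MRC reader is available among the package's R dependencies. Covers
# what the package needs: single volumes and image stacks with calibrated
# voxel size and origin; validated against an external reader in the tests.

#' Write a 3D array or image stack to an MRC2014 file
#'
#' @param grid numeric 3D array (x fastest) or a matrix (written as a
#'   single-section volume).
#' @param path output file.
#' @param voxel_size voxel edge length in Angstrom (isotropic).
#' @param origin physical origin (Angstrom, length 3), default c(0,0,0).
#' @param is_stack logical; if `TRUE` the z dimension is a stack of 2D
#'   images (ispg 0), otherwise a volume (ispg 1).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path, voxel_size, origin = c(0, 0, 0),
                      is_stack = FALSE) {
  if (is.matrix(grid)) grid <- array(grid, c(dim(grid), 1L))
  stopifnot(length(dim(grid)) == 3L, voxel_size > 0)
  d <- dim(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.vector(grid)
  wi(d)                              # nx ny nz
  wi(2L)                             # mode 2: float32
  wi(c(0L, 0L, 0L))                  # nxstart
  wi(d)                              # mx my mz
  wf(d * voxel_size)                 # cella
  wf(c(90, 90, 90))                  # cellb
  wi(c(1L, 2L, 3L))                  # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))     # dmin dmax dmean
  wi(if (is_stack) 0L else 1L)       # ispg
  wi(0L)                             # nsymbt
  wi(integer(25L))                   # extra (words 26-49)
  wf(origin)                         # origin (MRC2014, words 50-52)
  writeBin(charToRaw("MAP "), con)   # map id
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little endian
  wf(stats::sd(v))                   # rms
  wi(1L)                             # nlabl
  lab <- charToRaw(sprintf("%-80s", "vifhelix"))
  writeBin(lab, con)
  writeBin(raw(800L - length(lab)), con)
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC2014 file
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32), little endian.
#'
#' @param path MRC file.
#' @return A [density_map()] object (grid, voxel_size, origin, wedge NULL).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  ri(3L)                 # nxstart
  m <- ri(3L)            # mx my mz
  cella <- rf(3L)
  rf(3L)                 # cellb
  ri(3L)                 # mapc...
  rf(3L)                 # dmin dmax dmean
  ri(2L)                 # ispg nsymbt
  ri(25L)                # extra
  origin <- rf(3L)
  seek(con, 1024L)
  n <- prod(d)
  v <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2L,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    stop("unsupported MRC mode ", mode))
  if (length(v) != n) stop("truncated MRC data in ", path)
  voxel <- cella[1] / m[1]
  density_map(array(v, d), voxel_size = voxel, origin = origin)
}

#' Density map container
#'
#' A real-space 3D density grid with calibrated voxel size, physical origin
#' and an optional record of the missing-wedge corruption applied to it.
#'
#' @param grid numeric 3D array, x index fastest.
#' @param voxel_size voxel edge, Angstrom.
#' @param origin physical position of voxel (1,1,1), Angstrom.
#' @param wedge `NULL`, or the `(tilt_min, tilt_max)` degrees applied by
#'   [apply_missing_wedge()].
#' @return Object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0), wedge = NULL) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L, voxel_size > 0)
  m <- list(grid = grid, voxel_size = voxel_size, origin = origin,
            wedge = wedge)
  class(m) <- "density_map"
  m
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("Density map %d x %d x %d, voxel %.3g A%s\n", d[1], d[2], d[3],
              x$voxel_size,
              if (is.null(x$wedge)) ""
              else sprintf(", missing wedge outside tilts [%g, %g] deg",
                           x$wedge[1], x$wedge[2])))
  invisible(x)
}
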