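#' Helical symmetry parameters
#'
#' A helical assembly is described by the axial translation (rise, \eqn{h_r})
#' and rotation (twist) relating consecutive asymmetric units. The pitch
#' \eqn{P} (axial length of one full turn) and the number of asymmetric
#' units per pitch \eqn{n} obey \eqn{P = n \times h_r} and
#' \eqn{twist = 360 / n}. `units_per_pitch` is real-valued; intermediate
#' filaments have a non-integral n and no rounding is ever applied.
#'
#' @param rise axial translation per asymmetric unit, in Angstrom. Must be
#'   positive.
#' @param twist rotation per asymmetric unit, in degrees (0, 360].
#' @param handedness `+1` (right-handed, default) or `-1`. The hand cannot be
#'   read off a projection power spectrum, so the default is an arbitrary
#'   convention.
#' @return An object of class `helical_params` with fields `rise`, `twist`,
#'   `pitch`, `units_per_pitch` and `handedness` (lengths in Angstrom,
#'   angles in degrees).
#' @seealso [params_from_units()], [initial_symmetry_estimate()],
#'   [apply_operator()]
#' @examples
#' helical_params(rise = 42.5, twist = 73.7)
#' @export
helical_params <- function(rise, twist, handedness = 1L) {
  if (!is.numeric(rise) || length(rise) != 1L || !is.finite(rise) || rise <= 0)
    stop("'rise' must be a single positive number (Angstrom)")
  if (!is.numeric(twist) || length(twist) != 1L || !is.finite(twist) ||
      twist <= 0 || twist > 360)
    stop("'twist' must be a single number in (0, 360] degrees")
  if (!handedness %in% c(-1, 1))
    stop("'handedness' must be +1 or -1")
  n <- 360 / twist
  p <- list(rise = rise, twist = twist, pitch = n * rise,
            units_per_pitch = n, handedness = as.integer(handedness))
  class(p) <- "helical_params"
  validate_helical_params(p)
  p
}

validate_helical_params <- function(p) {
  stopifnot(inherits(p, "helical_params"))
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
  if (rel(p$pitch, p$units_per_pitch * p$rise) > 1e-9)
    stop("helical_params invariant violated: pitch != units_per_pitch * rise")
  if (rel(p$twist, 360 / p$units_per_pitch) > 1e-9)
    stop("helical_params invariant violated: twist != 360 / units_per_pitch")
  if (p$rise <= 0 || p$pitch <= 0 || p$twist <= 0 || p$twist > 360)
    stop("helical_params invariant violated: rise, pitch > 0 and 0 < twist <= 360")
  invisible(p)
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "Helical symmetry: rise %.4g A, twist %.4g deg (%s-handed)\n",
    x$rise, x$twist, if (x$handedness > 0) "right" else "left"))
  cat(sprintf("  pitch %.6g A, %.6g asymmetric units per pitch\n",
              x$pitch, x$units_per_pitch))
  invisible(x)
}

#' Helical parameters from units-per-pitch and rise
#'
#' Builds the symmetry record from the number of asymmetric units per pitch
#' (n, real-valued) and the rise, using twist = 360/n and pitch = n * rise.
#'
#' @param units_per_pitch asymmetric units per helical pitch (positive real).
#' @param rise axial rise per asymmetric unit, Angstrom.
#' @inheritParams helical_params
#' @return A [helical_params()] object.
#' @examples
#' params_from_units(5, 42)      # twist 72 deg, pitch 210 A
#' params_from_units(4.8824, 42.5)
#' @export
params_from_units <- function(units_per_pitch, rise, handedness = 1L) {
  if (!is.numeric(units_per_pitch) || length(units_per_pitch) != 1L ||
      !is.finite(units_per_pitch) || units_per_pitch <= 0)
    stop("'units_per_pitch' must be a single positive number")
  if (!is.numeric(rise) || length(rise) != 1L || !is.finite(rise) || rise <= 0)
    stop("'rise' must be a single positive number (Angstrom)")
  helical_params(rise = rise, twist = 360 / units_per_pitch,
                 handedness = handedness)
}

#' Initial symmetry estimate from protofibril count and axial period
#'
#' A filament built from `k` protofibrils, with the characteristic
#' intermediate-filament axial periodicity `axial_period`, has an initial
#' symmetry estimate of twist = 360/k and rise = axial_period/k: one
#' asymmetric unit per protofibril per period.
#'
#' @param n_protofibrils number of protofibrils (positive integer).
#' @param axial_period axial periodicity of the filament, Angstrom.
#' @return A [helical_params()] object.
#' @examples
#' initial_symmetry_estimate(5, 210)  # 72 deg / 42 A
#' initial_symmetry_estimate(5, 185)  # 72 deg / 37 A
#' @export
initial_symmetry_estimate <- function(n_protofibrils, axial_period) {
  if (!is.numeric(n_protofibrils) || length(n_protofibrils) != 1L ||
      !is.finite(n_protofibrils) || n_protofibrils < 1 ||
      n_protofibrils != round(n_protofibrils))
    stop("'n_protofibrils' must be a positive integer")
  if (!is.numeric(axial_period) || length(axial_period) != 1L ||
      !is.finite(axial_period) || axial_period <= 0)
    stop("'axial_period' must be a single positive number (Angstrom)")
  helical_params(rise = axial_period / n_protofibrils,
                 twist = 360 / n_protofibrils)
}

#' Mass per unit length of a helical filament
#'
#' The linear density of a helical polymer equals the mass of one asymmetric
#' unit divided by the helical rise.
#'
#' @param asymmetric_unit_mass mass of one asymmetric unit, kDa.
#' @param rise_nm helical rise, nm.
#' @return Linear density in kDa/nm.
#' @examples
#' mass_per_length(4 * vimentin_monomer_mass(), 4.25)  # ~50.5 kDa/nm
#' @export
mass_per_length <- function(asymmetric_unit_mass, rise_nm) {
  if (!is.numeric(asymmetric_unit_mass) || length(asymmetric_unit_mass) != 1L ||
      !is.finite(asymmetric_unit_mass) || asymmetric_unit_mass <= 0)
    stop("'asymmetric_unit_mass' must be a single positive number (kDa)")
  if (!is.numeric(rise_nm) || length(rise_nm) != 1L || !is.finite(rise_nm) ||
      rise_nm <= 0)
    stop("'rise_nm' must be a single positive number (nm)")
  asymmetric_unit_mass / rise_nm
}

#' Molecular mass of the human vimentin monomer
#'
#' The molecular weight of the full-length 466-residue human vimentin chain
#' (UniProt P08670), 53.652 kDa. Used to assign per-bead masses in the
#' lattice model (distributed in proportion to the residues each bead
#' represents) and to compute the filament mass per length.
#'
#' @return Monomer mass in kDa.
#' @export
vimentin_monomer_mass <- function() 53.652

#' Helical symmetry operator
#'
#' The k-th power of the screw operator of a helix: rotation by `k * twist`
#' about z and translation by `k * rise` along z. Power 0 is the identity,
#' and powers compose additively.
#'
#' @param params a [helical_params()] object.
#' @param k integer power of the operator.
#' @return A list with `rotation` (degrees, reduced mod 360), `translation`
#'   (Angstrom) and `repeat_index` k, of class `symmetry_operator`.
#' @export
symmetry_operator <- function(params, k = 1L) {
  validate_helical_params(params)
  if (!is.numeric(k) || length(k) != 1L || k != round(k))
    stop("'k' must be a single integer")
  op <- list(rotation = (params$handedness * k * params$twist) %% 360,
             translation = k * params$rise,
             repeat_index = as.integer(k))
  class(op) <- "symmetry_operator"
  op
}

#' Apply the helical symmetry operator to 3D points
#'
#' Rotates points by `k * twist` about the z axis (sign set by the
#' handedness) and translates them by `k * rise` along z. The operation is a
#' rigid motion: pairwise distances and cylindrical radii are preserved.
#'
#' @param points numeric matrix with 3 columns (x, y, z) in Angstrom, or a
#'   length-3 vector.
#' @param params a [helical_params()] object.
#' @param k integer power of the operator (may be negative).
#' @return Matrix of transformed coordinates, same shape as `points`.
#' @examples
#' p <- params_from_units(5, 42.5)
#' apply_operator(c(55, 0, 0), p, 5)  # one full turn: (55, 0, 212.5)
#' @export
apply_operator <- function(points, params, k = 1L) {
  validate_helical_params(params)
  if (!is.numeric(k) || length(k) != 1L || k != round(k))
    stop("'k' must be a single integer")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("'points' must have 3 columns (x, y, z)")
  if (!all(is.finite(points))) stop("'points' must be finite")
  theta <- params$handedness * k * params$twist * pi / 180
  ct <- cos(theta); st <- sin(theta)
  out <- points
  out[, 1L] <- ct * points[, 1L] - st * points[, 2L]
  out[, 2L] <- st * points[, 1L] + ct * points[, 2L]
  out[, 3L] <- points[, 3L] + k * params$rise
  out
}

#' Write helical parameters to a flat JSON record
#'
#' Serializes the symmetry as `{rise_A, twist_deg, pitch_A, n, handedness}`.
#'
#' @param params a [helical_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_helical_params <- function(params, path) {
  validate_helical_params(params)
  rec <- list(rise_A = params$rise, twist_deg = params$twist,
              pitch_A = params$pitch, n = params$units_per_pitch,
              handedness = params$handedness)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read helical parameters from a JSON record
#'
#' @param path file written by [write_helical_params()].
#' @return A [helical_params()] object.
#' @export
read_helical_params <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- helical_params(rise = rec$rise_A, twist = rec$twist_deg,
                      handedness = rec$handedness)
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
  if (rel(p$pitch, rec$pitch_A) > 1e-6 || rel(p$units_per_pitch, rec$n) > 1e-6)
    stop("inconsistent helical parameter record in ", path)
  p
}

#' Default vimentin filament symmetry
#'
#' The helical symmetry of vimentin intermediate filaments: rise 42.5 A,
#' twist 73.7 degrees (about 4.88 tetramers per 207.5 A pitch).
#'
#' @inheritParams helical_params
#' @return A [helical_params()] object.
#' @export
vif_params <- function(handedness = 1L) {
  helical_params(rise = 42.5, twist = 73.7, handedness = handedness)
}
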