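#' Triclinic unit cell and its reciprocal orthogonalization matrix
#'
#' Constructs a unit cell from the six lattice parameters and computes the
#' B matrix in the Busing--Levy frame: its columns are the reciprocal basis
#' vectors a*, b*, c* (crystallographic convention, no factor of 2\eqn{\pi}),
#' with a* along x and b* in the x--y plane. For any integer Miller triple
#' \code{h}, \code{cell$B \%*\% h} is that reflection's reciprocal vector in
#' inverse Angstroms.
#'
#' @param a,b,c axis lengths in Angstroms (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class \code{"unit_cell"}: a list with the six
#'   parameters, the cell \code{volume} (\eqn{\mathrm{\AA}^3}), the 3x3
#'   matrix \code{B} (\eqn{\mathrm{\AA}^{-1}}) and its inverse \code{Binv}.
#' @examples
#' uc <- unit_cell(64.3, 72.0, 89.2, 110.6, 107.5, 85.8)
#' uc$B %*% c(1, 0, 0)   # reciprocal vector of the (100) reflection
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            a > 0, b > 0, c > 0)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(.rad(alpha)); cb <- cos(.rad(beta)); cg <- cos(.rad(gamma))
  sa <- sin(.rad(alpha)); sb <- sin(.rad(beta)); sg <- sin(.rad(gamma))
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0)
    stop("invalid cell: angle combination gives non-positive volume")
  vol <- a * b * c * sqrt(arg)

  # reciprocal cell parameters
  as_ <- b * c * sa / vol
  bs_ <- a * c * sb / vol
  cs_ <- a * b * sg / vol
  cas <- (cb * cg - ca) / (sb * sg)
  cbs <- (ca * cg - cb) / (sa * sg)
  cgs <- (ca * cb - cg) / (sa * sb)
  sbs <- sqrt(pmax(0, 1 - cbs^2))
  sgs <- sqrt(pmax(0, 1 - cgs^2))

  # Busing-Levy B: a* along x, b* in the x-y plane
  B <- matrix(c(as_, 0, 0,
                bs_ * cgs, bs_ * sgs, 0,
                cs_ * cbs, -cs_ * sbs * ca, 1 / c), 3L, 3L)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 volume = vol, B = B, Binv = solve(B)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f A, alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("Volume: %.1f A^3\n", x$volume))
  invisible(x)
}

#' Photon energy to wavelength conversion
#'
#' @param energy photon energy in keV.
#' @return Wavelength in Angstroms, \eqn{\lambda = 12.398419 / E}.
#' @export
kev_to_angstrom <- function(energy) {
  stopifnot(all(energy > 0))
  12.398419 / energy
}

#' Two-colour beam setup
#'
#' Holds the pair of photon energies of a two-colour exposure and their
#' wavelengths. Equal energies are allowed and degrade the pipeline to
#' monochromatic behaviour.
#'
#' @param energies numeric vector of two photon energies in keV.
#' @return Object of class \code{"beam_setup"} with fields \code{energies}
#'   (keV) and \code{wavelengths} (Angstroms).
#' @examples
#' beam_setup(c(7, 9))
#' @export
beam_setup <- function(energies = c(7, 9)) {
  stopifnot(length(energies) == 2L, all(energies > 0))
  structure(list(energies = as.numeric(energies),
                 wavelengths = kev_to_angstrom(energies)),
            class = "beam_setup")
}

#' @export
print.beam_setup <- function(x, ...) {
  cat(sprintf("Beam: %.4g / %.4g keV (lambda = %.5f / %.5f A)\n",
              x$energies[1], x$energies[2],
              x$wavelengths[1], x$wavelengths[2]))
  invisible(x)
}

#' Flat single-panel detector geometry
#'
#' The laboratory frame is pinned as: beam along +z, detector plane
#' perpendicular to the beam at \code{distance}, fast axis along +x, slow
#' axis along +y. Pixel coordinates are 0-based with pixel centres at
#' integer positions; the default beam centre is the panel centre.
#'
#' @param n_fast,n_slow pixel counts along the fast and slow axes.
#' @param pixel_size pixel edge in metres.
#' @param distance sample-to-detector distance in metres.
#' @param beam_center length-2 vector (fast, slow) in pixels; default panel
#'   centre.
#' @return Object of class \code{"detector_geometry"}.
#' @export
detector_geometry <- function(n_fast = 1440L, n_slow = 1440L,
                              pixel_size = 100e-6, distance = 0.1,
                              beam_center = NULL) {
  stopifnot(n_fast >= 1, n_slow >= 1, pixel_size > 0, distance > 0)
  if (is.null(beam_center))
    beam_center <- c((n_fast - 1) / 2, (n_slow - 1) / 2)
  stopifnot(length(beam_center) == 2L)
  structure(list(n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
                 pixel_size = pixel_size, distance = distance,
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("Detector: %d x %d px, %.0f um pixels, %.4g m from sample, beam centre (%.1f, %.1f)\n",
              x$n_fast, x$n_slow, x$pixel_size * 1e6, x$distance,
              x$beam_center[1], x$beam_center[2]))
  invisible(x)
}
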