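#' Detector pixels to reciprocal-space vectors
#'
#' Converts detector peak positions to reciprocal vectors for an assumed
#' wavelength: with the incident wavevector \eqn{k_{in} = (0, 0, 1/\lambda)}
#' and \eqn{k_{out}} pointing from the sample to the pixel with
#' \eqn{|k_{out}| = 1/\lambda}, the scattering vector is
#' \eqn{q = k_{out} - k_{in}}. Every returned q lies exactly on the Ewald
#' sphere of the given wavelength.
#'
#' @param fs,ss fast/slow pixel coordinates (0-based, real-valued). \code{fs}
#'   may also be a 2-column matrix or data frame holding both.
#' @param geometry a \code{\link{detector_geometry}}.
#' @param wavelength wavelength in Angstroms.
#' @return n x 3 matrix of reciprocal vectors in \eqn{\mathrm{\AA}^{-1}}.
#' @examples
#' geom <- detector_geometry()
#' q <- pixel_to_q(900, 700, geom, kev_to_angstrom(7))
#' 1 / sqrt(sum(q^2))   # resolution d = 1/|q| in Angstroms
#' @export
pixel_to_q <- function(fs, ss = NULL, geometry, wavelength) {
  stopifnot(wavelength > 0)
  if (is.null(ss)) {
    fs <- as.matrix(fs)
    ss <- fs[, 2L]
    fs <- fs[, 1L]
  }
  x <- (fs - geometry$beam_center[1]) * geometry$pixel_size
  y <- (ss - geometry$beam_center[2]) * geometry$pixel_size
  z <- geometry$distance
  nrm <- sqrt(x^2 + y^2 + z^2)
  k <- 1 / wavelength
  cbind(k * x / nrm, k * y / nrm, k * (z / nrm - 1), deparse.level = 0)
}

#' Reciprocal vectors to detector pixels
#'
#' Inverse of \code{\link{pixel_to_q}} for vectors on (or near) the Ewald
#' sphere: the outgoing direction \eqn{k_{out} = q + k_{in}} is intersected
#' with the detector plane. Reflections with \eqn{|q| > 2/\lambda} cannot be
#' excited at this wavelength and are flagged unreachable; intersections
#' outside the panel (or scattered into the back hemisphere) are flagged
#' off-detector rather than raising an error.
#'
#' @param q n x 3 matrix of reciprocal vectors (\eqn{\mathrm{\AA}^{-1}}).
#' @param geometry a \code{\link{detector_geometry}}.
#' @param wavelength wavelength in Angstroms.
#' @return Data frame with columns \code{fs}, \code{ss} (pixels; \code{NA}
#'   when not projectable), \code{on_detector}, \code{reachable}.
#' @export
q_to_pixel <- function(q, geometry, wavelength) {
  stopifnot(wavelength > 0)
  q <- matrix(as.numeric(q), ncol = 3L)
  k <- 1 / wavelength
  qn <- .row_norms(q)
  reachable <- qn <= 2 * k * (1 + 1e-12)
  kz <- q[, 3L] + k
  forward <- kz > 1e-12 * k
  ok <- reachable & forward
  fs <- ss <- rep(NA_real_, nrow(q))
  scale <- geometry$distance / kz[ok]
  fs[ok] <- q[ok, 1L] * scale / geometry$pixel_size + geometry$beam_center[1]
  ss[ok] <- q[ok, 2L] * scale / geometry$pixel_size + geometry$beam_center[2]
  on <- ok & !is.na(fs) &
    fs >= 0 & fs <= geometry$n_fast - 1 &
    ss >= 0 & ss <= geometry$n_slow - 1
  on[is.na(on)] <- FALSE
  data.frame(fs = fs, ss = ss, on_detector = on, reachable = reachable)
}
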