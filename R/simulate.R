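#' Simulation configuration for two-colour still patterns
#'
#' Bundles the crystal, detector and beam description of the geometric
#' diffraction model: reciprocal-lattice points are spheres of fixed radius,
#' and a reflection is excited when either colour's Ewald sphere intercepts
#' its sphere. Structure factors, excitation-error weighting and detector
#' noise are deliberately absent from the model. The defaults reproduce the
#' validation conditions: triclinic P1 cell a=64.3, b=72.0, c=89.2 A,
#' alpha=110.6, beta=107.5, gamma=85.8 deg; 1440 x 1440 detector with
#' 100 um pixels 0.1 m downstream; 7 and 9 keV photon energies.
#'
#' @param cell a \code{\link{unit_cell}}.
#' @param geometry a \code{\link{detector_geometry}}.
#' @param beam a \code{\link{beam_setup}}.
#' @param sphere_radius lattice-point radius in \eqn{\mathrm{\AA}^{-1}}
#'   (default 0.0015); must be well below the shortest reciprocal axis.
#' @param d_min resolution cutoff of the simulated reflections, Angstroms
#'   (default 3).
#' @param pixel_jitter optional Gaussian jitter (sd, pixels) added to spot
#'   centroids; 0 (default) gives noise-free positions.
#' @param n_patterns default dataset size for
#'   \code{\link{simulate_dataset}} (default 100).
#' @return Object of class \code{"simulation_config"}; reference
#'   reflections are enumerated once and cached in the object.
#' @export
simulation_config <- function(cell = unit_cell(64.3, 72.0, 89.2,
                                               110.6, 107.5, 85.8),
                              geometry = detector_geometry(),
                              beam = beam_setup(c(7, 9)),
                              sphere_radius = 0.0015, d_min = 3,
                              pixel_jitter = 0, n_patterns = 100L) {
  stopifnot(sphere_radius > 0, d_min > 0, pixel_jitter >= 0, n_patterns >= 1)
  shortest_axis <- min(.row_norms(t(cell$B)))
  if (sphere_radius > 0.2 * shortest_axis)
    stop("sphere_radius must be much smaller than the shortest reciprocal axis")
  refl <- enumerate_reflections(cell, d_min)
  structure(list(cell = cell, geometry = geometry, beam = beam,
                 sphere_radius = sphere_radius, d_min = d_min,
                 pixel_jitter = pixel_jitter,
                 n_patterns = as.integer(n_patterns),
                 reflections = refl),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Two-colour simulation config\n")
  print(x$cell); print(x$geometry); print(x$beam)
  cat(sprintf("sphere radius %.2g 1/A, d_min %.3g A, %d reflections, %d patterns\n",
              x$sphere_radius, x$d_min, nrow(x$reflections), x$n_patterns))
  invisible(x)
}

#' Uniformly random crystal orientations
#'
#' Samples proper rotations uniformly over SO(3) by normalizing a 4-vector
#' of standard normals to a unit quaternion. Uses the current RNG stream;
#' call \code{set.seed} for reproducibility.
#'
#' @param n number of rotations.
#' @return A 3 x 3 matrix for \code{n = 1}, otherwise a list of matrices.
#' @export
random_orientation <- function(n = 1L) {
  one <- function() {
    v <- stats::rnorm(4L)
    v <- v / sqrt(sum(v * v))
    w <- v[1L]; x <- v[2L]; y <- v[3L]; z <- v[4L]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3L, 3L)
  }
  if (n == 1L) one() else replicate(n, one(), simplify = FALSE)
}

#' Euler angles (intrinsic z-y-x) to and from rotation matrices
#'
#' The convention is pinned throughout the package:
#' \eqn{R = R_z(\alpha) R_y(\beta) R_x(\gamma)} with angles in degrees.
#'
#' @param angles length-3 numeric vector (degrees).
#' @return \code{euler_to_matrix}: 3 x 3 rotation; \code{matrix_to_euler}:
#'   length-3 vector of degrees.
#' @export
euler_to_matrix <- function(angles) {
  a <- .rad(angles[1L]); b <- .rad(angles[2L]); g <- .rad(angles[3L])
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3L, 3L)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3L, 3L)
  Rz %*% Ry %*% Rx
}

#' @rdname euler_to_matrix
#' @param R 3 x 3 proper rotation matrix.
#' @export
matrix_to_euler <- function(R) {
  if (abs(R[3L, 1L]) < 1 - 1e-12) {
    b <- asin(-R[3L, 1L])
    a <- atan2(R[2L, 1L], R[1L, 1L])
    g <- atan2(R[3L, 2L], R[3L, 3L])
  } else {                         # gimbal lock: pin gamma = 0
    b <- if (R[3L, 1L] < 0) pi / 2 else -pi / 2
    g <- 0
    a <- atan2(-R[1L, 2L], R[2L, 2L])
  }
  .deg(c(a, b, g))
}

#' Simulate one two-colour still diffraction pattern
#'
#' Rotates every reference reflection by the true orientation, excites those
#' whose distance to either colour's Ewald sphere surface is at most the
#' sphere radius, snaps each excited point radially onto the intercepting
#' sphere (the detector records where the sphere cuts the spot) and
#' projects it to pixel coordinates; off-detector intersections are
#' dropped. A reflection excited by both colours produces one spot per
#' colour, both flagged \code{dual}. Intensities and SNR are set to 1 --
#' the geometric model carries no physical intensities.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param U_true 3 x 3 proper rotation (the ground-truth orientation).
#' @return Object of class \code{"sim_pattern"}: \code{U_true}, the
#'   \code{peaks} data frame (fs, ss, intensity, snr, true_color, h, k, l,
#'   dual), the per-peak on-sphere \code{q_true}, and the count of spots
#'   dropped off-detector. Zero excited spots is a valid, flagged outcome.
#' @export
simulate_pattern <- function(config, U_true) {
  stopifnot(inherits(config, "simulation_config"), .is_rotation(U_true, 1e-6))
  refl <- config$reflections
  Q <- as.matrix(refl[, c("qx", "qy", "qz")]) %*% t(U_true)
  k <- 1 / config$beam$wavelengths
  dist <- sapply(1:2, function(j)
    sqrt(Q[, 1L]^2 + Q[, 2L]^2 + (Q[, 3L] + k[j])^2) - k[j])
  out <- list()
  n_dropped <- 0L
  for (j in 1:2) {
    sel <- which(abs(dist[, j]) <= config$sphere_radius)
    if (!length(sel)) next
    centre <- c(0, 0, -k[j])
    V <- sweep(Q[sel, , drop = FALSE], 2L, centre)
    Qon <- sweep(V * (k[j] / .row_norms(V)), 2L, centre, `+`)
    px <- q_to_pixel(Qon, config$geometry, config$beam$wavelengths[j])
    if (config$pixel_jitter > 0) {
      px$fs <- px$fs + stats::rnorm(nrow(px), 0, config$pixel_jitter)
      px$ss <- px$ss + stats::rnorm(nrow(px), 0, config$pixel_jitter)
    }
    keep <- px$on_detector
    n_dropped <- n_dropped + sum(!keep)
    if (!any(keep)) next
    sel <- sel[keep]
    out[[j]] <- data.frame(fs = px$fs[keep], ss = px$ss[keep],
                           intensity = 1, snr = 1,
                           true_color = j,
                           h = refl$h[sel], k = refl$k[sel], l = refl$l[sel],
                           dual = abs(dist[sel, 3L - j]) <= config$sphere_radius,
                           qx = Qon[keep, 1L], qy = Qon[keep, 2L],
                           qz = Qon[keep, 3L])
  }
  peaks <- do.call(rbind, out)
  if (is.null(peaks)) {
    peaks <- data.frame(fs = numeric(), ss = numeric(), intensity = numeric(),
                        snr = numeric(), true_color = integer(),
                        h = integer(), k = integer(), l = integer(),
                        dual = logical(), qx = numeric(), qy = numeric(),
                        qz = numeric())
  }
  q_true <- as.matrix(peaks[, c("qx", "qy", "qz")])
  peaks <- peaks[, setdiff(names(peaks), c("qx", "qy", "qz"))]
  class(peaks) <- c("peak_list", "data.frame")
  structure(list(U_true = U_true, peaks = peaks, q_true = q_true,
                 n_dropped = n_dropped, empty = nrow(peaks) == 0L,
                 config_d_min = config$d_min,
                 sphere_radius = config$sphere_radius),
            class = "sim_pattern")
}

#' @export
print.sim_pattern <- function(x, ...) {
  tc <- table(factor(x$peaks$true_color, levels = 1:2))
  cat(sprintf("Simulated pattern: %d peaks (%d colour-1, %d colour-2, %d dual-excitable), %d dropped off-detector\n",
              nrow(x$peaks), tc[1L], tc[2L], sum(x$peaks$dual), x$n_dropped))
  invisible(x)
}

#' Simulate a dataset of two-colour patterns
#'
#' Draws \code{n_patterns} independent uniform orientations from the current
#' RNG stream and simulates one pattern per orientation.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param n_patterns number of patterns (default from the config).
#' @return Object of class \code{"sim_dataset"}: list of
#'   \code{\link{simulate_pattern}} results plus a truth manifest of the
#'   orientations.
#' @export
simulate_dataset <- function(config, n_patterns = config$n_patterns) {
  patterns <- vector("list", n_patterns)
  for (i in seq_len(n_patterns))
    patterns[[i]] <- simulate_pattern(config, random_orientation())
  structure(list(patterns = patterns, config = config,
                 n_patterns = n_patterns),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  np <- vapply(x$patterns, function(p) nrow(p$peaks), integer(1L))
  cat(sprintf("Simulated dataset: %d patterns, %.1f peaks/pattern (range %d-%d)\n",
              x$n_patterns, mean(np), min(np), max(np)))
  invisible(x)
}
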