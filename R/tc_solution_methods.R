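#' @export
print.tc_solution <- function(x, ...) {
  cat(sprintf("Two-colour indexing solution (%.4g / %.4g keV)\n",
              x$beam$energies[1], x$beam$energies[2]))
  cat(sprintf("  matched %d / %d peaks (delta = %g)\n",
              x$score, x$n_peaks, x$params$delta))
  n_un <- x$n_peaks - length(x$group_1) - length(x$group_2)
  cat(sprintf("  colour groups: %d / %d peaks, %d unassigned\n",
              length(x$group_1), length(x$group_2), n_un))
  cat(sprintf("  refinement objective: %.4g -> %.4g%s\n",
              x$refinement$objective0, x$refinement$objective,
              if (isTRUE(x$refinement$reverted)) " (reverted)" else ""))
  cat("  rotation U:\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' @export
summary.tc_solution <- function(object, ...) {
  asg <- object$assignments
  out <- list(score = object$score, n_peaks = object$n_peaks,
              n_group_1 = length(object$group_1),
              n_group_2 = length(object$group_2),
              n_unassigned = sum(is.na(asg$assigned_color)),
              residual_quantiles = stats::quantile(
                pmin(asg$residual_1, asg$residual_2),
                c(0.5, 0.9, 0.99)),
              refinement = object$refinement,
              rotation = object$rotation)
  class(out) <- "summary.tc_solution"
  out
}

#' @export
print.summary.tc_solution <- function(x, ...) {
  cat(sprintf("Two-colour solution: S = %d / %d (groups %d / %d, %d unassigned)\n",
              x$score, x$n_peaks, x$n_group_1, x$n_group_2, x$n_unassigned))
  cat("Min-colour residual quantiles:\n")
  print(round(x$residual_quantiles, 4))
  cat(sprintf("Refinement: %.4g -> %.4g in %d evaluations\n",
              x$refinement$objective0, x$refinement$objective,
              x$refinement$iterations))
  invisible(x)
}

#' @export
residuals.tc_solution <- function(object, ...)
  pmin(object$assignments$residual_1, object$assignments$residual_2)

#' Detector-space view of a classified pattern
#'
#' Plots the peak positions coloured by assigned colour group (base
#' graphics); unassigned peaks are grey.
#'
#' @param x a \code{tc_solution}.
#' @param ... passed to \code{plot}.
#' @export
plot.tc_solution <- function(x, ...) {
  asg <- x$assignments$assigned_color
  col <- ifelse(is.na(asg), "grey60", ifelse(asg == 1L, "darkorange", "steelblue"))
  plot(x$peaks$fs, x$peaks$ss, col = col, pch = 16, cex = 0.6,
       xlab = "fast (px)", ylab = "slow (px)", asp = 1,
       xlim = c(0, x$geometry$n_fast - 1), ylim = c(0, x$geometry$n_slow - 1),
       ...)
  graphics::legend("topright", bty = "n", pch = 16,
                   col = c("darkorange", "steelblue", "grey60"),
                   legend = c(sprintf("%.4g keV", x$beam$energies[1]),
                              sprintf("%.4g keV", x$beam$energies[2]),
                              "unassigned"))
  invisible(x)
}

#' Predicted reflection positions for an indexed pattern
#'
#' Projects every reference reflection excited under either colour at the
#' fitted orientation back onto the detector, using the same
#' Ewald-interception model as the simulator.
#'
#' @param object a \code{tc_solution}.
#' @param d_min resolution cutoff for the prediction (Angstroms).
#' @param sphere_radius excitation radius around each lattice point,
#'   \eqn{\mathrm{\AA}^{-1}}.
#' @param ... unused.
#' @return Data frame of predicted spots: \code{fs}, \code{ss},
#'   \code{color}, \code{h}, \code{k}, \code{l}.
#' @export
predict.tc_solution <- function(object, d_min = 3, sphere_radius = 0.0015,
                                ...) {
  cfg <- simulation_config(cell = object$cell, geometry = object$geometry,
                           beam = object$beam, d_min = d_min,
                           sphere_radius = sphere_radius)
  pat <- simulate_pattern(cfg, object$rotation)
  out <- pat$peaks[, c("fs", "ss", "true_color", "h", "k", "l")]
  names(out)[3L] <- "color"
  out
}
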