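#' Orientation error between two rotations
#'
#' Total error is the rotation angle of \eqn{U_{est} U_{true}'}; per-Euler
#' errors are absolute circular differences of the two decompositions in the
#' package's pinned intrinsic z-y-x convention. For a triclinic P1 lattice
#' the proper rotation group is trivial, so no symmetry-equivalent
#' minimization applies.
#'
#' @param U_est,U_true 3 x 3 proper rotation matrices.
#' @return List with \code{total} (degrees) and \code{euler_abs}
#'   (length-3 vector of absolute per-Euler-angle errors, degrees).
#' @export
orientation_error <- function(U_est, U_true) {
  if (!.is_rotation(U_est, 1e-6) || !.is_rotation(U_true, 1e-6))
    stop("orientation_error requires proper rotation matrices")
  D <- U_est %*% t(U_true)
  total <- .deg(acos(.clamp((sum(diag(D)) - 1) / 2, -1, 1)))
  de <- abs(matrix_to_euler(U_est) - matrix_to_euler(U_true))
  de <- pmin(de, 360 - de)
  list(total = total, euler_abs = de)
}

#' Evaluate indexing solutions against simulation ground truth
#'
#' Aggregates orientation accuracy and colour-classification metrics over a
#' dataset: indexing rate, total angular and per-Euler-angle errors (with
#' medians and the fraction exceeding 0.2 degrees), the correctly-oriented
#' count at a threshold, and colour accuracy over unambiguous
#' (non-dual-excitable) matched peaks.
#'
#' @param solutions list of \code{\link{index_two_color}} results (may
#'   contain \code{NULL} for unindexed patterns), same order as the dataset.
#' @param dataset a \code{\link{simulate_dataset}} result.
#' @param correct_threshold total angular error (degrees) below which an
#'   indexed pattern counts as correctly oriented (default 1).
#' @return Object of class \code{"tc_eval"}.
#' @export
evaluate_dataset <- function(solutions, dataset, correct_threshold = 1) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (length(solutions) != dataset$n_patterns)
    stop("pattern id mismatch: ", length(solutions), " solutions for ",
         dataset$n_patterns, " patterns")
  n <- dataset$n_patterns
  indexed <- !vapply(solutions, is.null, logical(1L))
  total_err <- rep(NA_real_, n)
  euler_err <- matrix(NA_real_, n, 3L)
  n_color_ok <- 0L; n_color_all <- 0L; n_dual <- 0L; n_peaks_tot <- 0L
  for (i in seq_len(n)) {
    pat <- dataset$patterns[[i]]
    n_peaks_tot <- n_peaks_tot + nrow(pat$peaks)
    n_dual <- n_dual + sum(pat$peaks$dual)
    if (!indexed[i]) next
    sol <- solutions[[i]]
    err <- orientation_error(sol$rotation, pat$U_true)
    total_err[i] <- err$total
    euler_err[i, ] <- err$euler_abs
    asg <- sol$assignments$assigned_color
    use <- !is.na(asg) & !pat$peaks$dual
    n_color_all <- n_color_all + sum(use)
    n_color_ok <- n_color_ok + sum(asg[use] == pat$peaks$true_color[use])
  }
  ee <- euler_err[indexed, , drop = FALSE]
  structure(list(
    n_total = n, n_indexed = sum(indexed),
    indexing_rate = mean(indexed),
    n_correct = sum(total_err < correct_threshold, na.rm = TRUE),
    correct_threshold = correct_threshold,
    total_error = total_err, euler_error = euler_err,
    median_total_error = stats::median(total_err[indexed]),
    median_euler_error = stats::median(as.numeric(ee)),
    frac_euler_above_0.2 = if (length(ee)) mean(as.numeric(ee) > 0.2) else NA_real_,
    color_accuracy = if (n_color_all) n_color_ok / n_color_all else NA_real_,
    n_color_checked = n_color_all,
    n_dual_excitable = n_dual,
    mean_peaks_per_pattern = n_peaks_tot / n),
    class = "tc_eval")
}

#' @export
print.tc_eval <- function(x, ...) {
  cat(sprintf("Indexed %d / %d patterns (rate %.3f); %d within %.2g deg of truth\n",
              x$n_indexed, x$n_total, x$indexing_rate, x$n_correct,
              x$correct_threshold))
  cat(sprintf("Median per-Euler-angle error: %.4g deg (%.1f%% above 0.2 deg)\n",
              x$median_euler_error, 100 * x$frac_euler_above_0.2))
  cat(sprintf("Colour accuracy over %d unambiguous matched peaks: %.4f (%d dual-excitable excluded)\n",
              x$n_color_checked, x$color_accuracy, x$n_dual_excitable))
  cat(sprintf("Mean peaks/pattern: %.1f\n", x$mean_peaks_per_pattern))
  invisible(x)
}

#' Utility versus search budget
#'
#' Re-indexes a simulated dataset at several top-k pair budgets and reports
#' the utility: the fraction of indexable patterns (those with at least 6
#' peaks) actually indexed at each budget.
#'
#' @param dataset a \code{\link{simulate_dataset}} result.
#' @param table a \code{\link{reference_table}}.
#' @param n_pairs integer vector of pair budgets to sweep.
#' @param params base \code{\link{indexer_params}}; \code{n_pairs} is
#'   overridden per sweep point.
#' @return Data frame with columns \code{n_pairs}, \code{n_indexable},
#'   \code{n_indexed}, \code{utility}.
#' @export
utility_sweep <- function(dataset, table, n_pairs = c(1L, 2L, 5L),
                          params = indexer_params()) {
  indexable <- vapply(dataset$patterns, function(p) nrow(p$peaks) >= 6L,
                      logical(1L))
  out <- lapply(n_pairs, function(k) {
    p <- params; p$n_pairs <- as.integer(k)
    idx <- vapply(dataset$patterns[indexable], function(pat)
      !is.null(index_two_color(pat$peaks, table, dataset$config$geometry,
                               dataset$config$beam, p)), logical(1L))
    data.frame(n_pairs = k, n_indexable = sum(indexable),
               n_indexed = sum(idx), utility = mean(idx))
  })
  do.call(rbind, out)
}
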