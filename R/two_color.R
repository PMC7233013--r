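#' Two-colour scoring of an orientation
#'
#' Each detector peak is converted under both wavelengths, giving two
#' candidate reciprocal vectors per peak; the fractional-index residual is
#' evaluated under each colour and a peak matched to either colour counts as
#' matched. The two-colour score is therefore never below either
#' monochromatic score for the same rotation.
#'
#' @param U 3 x 3 proper rotation.
#' @param cell a \code{\link{unit_cell}}.
#' @param q1,q2 n x 3 matrices: the SAME detector peaks converted under
#'   wavelengths 1 and 2 (row i of both is one peak).
#' @param delta matching threshold (default 0.25).
#' @return List with \code{score}, and vectors \code{residual_1},
#'   \code{residual_2}, \code{matched}.
#' @export
score_two_color <- function(U, cell, q1, q2, delta = 0.25) {
  stopifnot(nrow(q1) == nrow(q2))
  s1 <- score_solution(U, cell, q1, delta)
  s2 <- score_solution(U, cell, q2, delta)
  r1 <- s1$records$residual
  r2 <- s2$records$residual
  matched <- pmin(r1, r2) <= delta
  list(score = sum(matched), residual_1 = r1, residual_2 = r2,
       matched = matched)
}

#' Per-peak colour probabilities from residual pairs
#'
#' The probability that peak i originates from colour j is the inverse
#' residual share: \eqn{p_{i,1} = e_{i,2} / (e_{i,1} + e_{i,2})} and
#' \eqn{p_{i,2} = e_{i,1} / (e_{i,1} + e_{i,2})}, so the colour with the
#' smaller fractional-index deviation receives the larger probability and
#' the two always sum to one (both residuals zero gives 0.5/0.5). A peak is
#' assigned to the colour whose probability exceeds 0.5; peaks with both
#' residuals above \code{delta} stay unassigned with probabilities still
#' reported.
#'
#' @param residual_1,residual_2 per-peak max-component fractional-index
#'   deviations under the two colours, each in [0, 0.5].
#' @param delta matching threshold (default 0.25).
#' @return Data frame with columns \code{peak}, \code{residual_1},
#'   \code{residual_2}, \code{p_1}, \code{p_2}, \code{matched},
#'   \code{assigned_color} (1, 2 or \code{NA}).
#' @export
assign_color_probabilities <- function(residual_1, residual_2, delta = 0.25) {
  stopifnot(length(residual_1) == length(residual_2),
            all(residual_1 >= 0), all(residual_2 >= 0),
            all(residual_1 <= 0.5 + 1e-12), all(residual_2 <= 0.5 + 1e-12))
  tot <- residual_1 + residual_2
  p1 <- ifelse(tot > 0, residual_2 / tot, 0.5)
  p2 <- 1 - p1
  matched <- pmin(residual_1, residual_2) <= delta
  assigned <- rep(NA_integer_, length(p1))
  assigned[matched & p1 > 0.5] <- 1L
  assigned[matched & p2 > 0.5] <- 2L
  data.frame(peak = seq_along(p1),
             residual_1 = residual_1, residual_2 = residual_2,
             p_1 = p1, p_2 = p2, matched = matched,
             assigned_color = assigned)
}

#' Global refinement of a two-colour orientation
#'
#' Minimizes the summed squared fractional Miller-index deviations of the
#' colour-1 group under wavelength 1 and the colour-2 group under
#' wavelength 2, over proper rotations only (the prior cell stays fixed).
#' The rotation is parametrized as an axis-angle perturbation composed with
#' the start \code{U0}, so every evaluated matrix is exactly orthonormal,
#' and the integer index targets are frozen at their \code{U0} values. If
#' the optimizer fails to improve the objective, \code{U0} is returned with
#' a warning flag -- never a worse solution.
#'
#' @param U0 3 x 3 starting rotation.
#' @param cell a \code{\link{unit_cell}}.
#' @param q_group1 reciprocal vectors (rows) of colour-1 peaks under
#'   wavelength 1.
#' @param q_group2 reciprocal vectors of colour-2 peaks under wavelength 2;
#'   may have zero rows.
#' @param maxit optimizer iteration cap.
#' @return List: refined \code{U}, \code{objective0}, \code{objective},
#'   \code{iterations}, \code{converged}, \code{reverted}.
#' @export
refine_solution <- function(U0, cell, q_group1,
                            q_group2 = matrix(numeric(), 0L, 3L),
                            maxit = 200L) {
  stopifnot(.is_rotation(U0, tol = 1e-6))
  q_group1 <- matrix(as.numeric(q_group1), ncol = 3L)
  q_group2 <- matrix(as.numeric(q_group2), ncol = 3L)
  n_tot <- nrow(q_group1) + nrow(q_group2)
  Binv <- cell$Binv
  frac_at <- function(U, q)
    if (nrow(q)) t(Binv %*% t(U) %*% t(q)) else matrix(numeric(), 0L, 3L)
  H1 <- .round_half_away(frac_at(U0, q_group1))
  H2 <- .round_half_away(frac_at(U0, q_group2))
  obj <- function(w) {
    U <- .axis_angle_matrix(w) %*% U0
    sum((frac_at(U, q_group1) - H1)^2) + sum((frac_at(U, q_group2) - H2)^2)
  }
  f0 <- obj(c(0, 0, 0))
  if (n_tot < 3L)
    return(list(U = U0, objective0 = f0, objective = f0, iterations = 0L,
                converged = FALSE, reverted = TRUE))
  opt <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  if (is.finite(opt$value) && opt$value <= f0) {
    list(U = .axis_angle_matrix(opt$par) %*% U0,
         objective0 = f0, objective = opt$value,
         iterations = unname(opt$counts[1L]),
         converged = opt$convergence == 0L, reverted = FALSE)
  } else {
    warning("refinement did not improve the objective; keeping the unrefined rotation")
    list(U = U0, objective0 = f0, objective = f0,
         iterations = unname(opt$counts[1L]), converged = FALSE,
         reverted = TRUE)
  }
}

#' Index a two-colour diffraction pattern
#'
#' The central fitting routine. Peaks are converted to reciprocal vectors
#' under both wavelengths; the reference-table search (pair selection,
#' tolerance query, pair-rotation solving) is run independently under each
#' colour; every surviving rotation candidate from both searches is scored
#' with the two-colour rule (a peak matched to either colour counts); the
#' best candidate is kept, peaks receive colour probabilities and are split
#' into two colour groups, and the rotation is globally refined over the
#' groups and re-scored.
#'
#' @param peaks a \code{\link{peak_list}} (or data frame with columns
#'   \code{fs}, \code{ss}, \code{intensity}, \code{snr}).
#' @param table a \code{\link{reference_table}} built from the prior cell.
#' @param geometry a \code{\link{detector_geometry}}.
#' @param beam a \code{\link{beam_setup}}.
#' @param params an \code{\link{indexer_params}}.
#' @return Object of class \code{c("tc_solution", "index_solution")}, or
#'   \code{NULL} when the pattern is not indexable (fewer than 2 peaks, no
#'   candidates, or best score below \code{min_score}). Fields include the
#'   refined \code{rotation}, two-colour \code{score}, per-peak
#'   \code{assignments} (residuals, probabilities, assigned colour),
#'   \code{group_1}/\code{group_2} peak ids, and a \code{refinement} report.
#' @examples
#' \donttest{
#' cell <- unit_cell(64.3, 72.0, 89.2, 110.6, 107.5, 85.8)
#' tab <- reference_table(cell, d_min = 5)
#' cfg <- simulation_config(cell = cell, d_min = 5)
#' set.seed(1)
#' pat <- simulate_pattern(cfg, random_orientation())
#' sol <- index_two_color(pat$peaks, tab, cfg$geometry, cfg$beam)
#' sol
#' }
#' @export
index_two_color <- function(peaks, table, geometry, beam,
                            params = indexer_params()) {
  if (is.null(peaks) || nrow(peaks) < 2L) return(NULL)
  q1 <- pixel_to_q(peaks$fs, peaks$ss, geometry, beam$wavelengths[1L])
  q2 <- pixel_to_q(peaks$fs, peaks$ss, geometry, beam$wavelengths[2L])
  res <- .index_core(list(q1, q2), peaks, table, params, two_colour = TRUE)
  if (is.null(res)) return(NULL)
  U0 <- res$cand$U
  cell <- table$cell

  build <- function(U) {
    sc <- score_two_color(U, cell, q1, q2, params$delta)
    asg <- assign_color_probabilities(sc$residual_1, sc$residual_2,
                                      params$delta)
    list(score = sc$score, assignments = asg,
         group_1 = asg$peak[!is.na(asg$assigned_color) & asg$assigned_color == 1L],
         group_2 = asg$peak[!is.na(asg$assigned_color) & asg$assigned_color == 2L])
  }
  st0 <- build(U0)
  ref <- refine_solution(U0, cell, q1[st0$group_1, , drop = FALSE],
                         q2[st0$group_2, , drop = FALSE])
  st <- build(ref$U)
  if (st$score < st0$score) {         # never return a worse solution
    ref$U <- U0
    ref$reverted <- TRUE
    st <- st0
  }
  if (st$score < .min_score(params, nrow(q1))) return(NULL)
  structure(list(rotation = ref$U, score = st$score,
                 assignments = st$assignments,
                 group_1 = st$group_1, group_2 = st$group_2,
                 refinement = ref[c("objective0", "objective", "iterations",
                                    "converged", "reverted")],
                 seed_pair = res$cand$seed_pair,
                 seed_hkl = res$cand$hkl_pair,
                 seed_colour = res$cand$colour,
                 peaks = peaks, cell = cell, geometry = geometry,
                 beam = beam, params = params, n_peaks = nrow(q1)),
            class = c("tc_solution", "index_solution"))
}
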