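#' Indexer tuning parameters
#'
#' @param delta fractional Miller-index threshold: a peak is matched when
#'   the largest component deviation from the nearest integers is at most
#'   \code{delta} (default 0.25; must be in (0, 0.5]).
#' @param n_pairs number of top-ranked peak pairs used as matching seeds
#'   (default 5).
#' @param sort_key ranking key for peak pairs: \code{"snr"} (default),
#'   \code{"intensity"} (both descending by the pair's summed key) or
#'   \code{"resolution"} (best resolution first, i.e. ascending summed
#'   d-spacing).
#' @param tol_len length tolerance for table queries,
#'   \eqn{\mathrm{\AA}^{-1}} (default 0.0025).
#' @param tol_angle angle tolerance for table queries, degrees (default 1).
#' @param min_score minimum matched-peak count for an acceptable solution;
#'   \code{NULL} (default) uses \eqn{\max(6, \lceil 0.4 N \rceil)} for a
#'   pattern of N peaks, which stops two-peak self-matches from "indexing"
#'   noise.
#' @param prescore_peaks size of the resolution-stratified peak subset used
#'   in the first scoring stage (default 60); patterns with at most this
#'   many peaks are scored in a single exact stage.
#' @param shortlist number of candidates per (pair, colour) query carried
#'   into full scoring (default 50).
#' @return Object of class \code{"indexer_params"}.
#' @export
indexer_params <- function(delta = 0.25, n_pairs = 5L,
                           sort_key = c("snr", "intensity", "resolution"),
                           tol_len = 0.0025, tol_angle = 1,
                           min_score = NULL,
                           prescore_peaks = 60L, shortlist = 50L) {
  sort_key <- match.arg(sort_key)
  stopifnot(delta > 0, delta <= 0.5, n_pairs >= 1,
            tol_len >= 0, tol_angle >= 0,
            prescore_peaks >= 2, shortlist >= 1)
  structure(list(delta = delta, n_pairs = as.integer(n_pairs),
                 sort_key = sort_key, tol_len = tol_len,
                 tol_angle = tol_angle, min_score = min_score,
                 prescore_peaks = as.integer(prescore_peaks),
                 shortlist = as.integer(shortlist)),
            class = "indexer_params")
}

.min_score <- function(params, n_peaks)
  params$min_score %||% max(6L, ceiling(0.4 * n_peaks))

#' Peak list constructor
#'
#' @param fs,ss detector pixel coordinates (0-based).
#' @param intensity,snr per-peak intensity and signal-to-noise ratio; both
#'   default to 1 (the noise-free simulator carries no physical
#'   intensities).
#' @param ... further per-peak columns (e.g. simulation truth) appended
#'   verbatim.
#' @return Data frame of class \code{"peak_list"}.
#' @export
peak_list <- function(fs, ss, intensity = 1, snr = 1, ...) {
  stopifnot(length(fs) == length(ss), all(snr >= 0, na.rm = TRUE))
  structure(data.frame(fs = fs, ss = ss,
                       intensity = rep_len(intensity, length(fs)),
                       snr = rep_len(snr, length(fs)), ...),
            class = c("peak_list", "data.frame"))
}

#' Rank peak pairs for seed selection
#'
#' All unordered pairs are ranked by the chosen key -- the pair key is the
#' sum of the two peaks' key values, descending for intensity/SNR and
#' ascending summed d-spacing for resolution -- and truncated to
#' \code{n_pairs}. When lengths are supplied, key ties are broken toward
#' pairs whose vector lengths lie closest to \code{preferred_length}
#' (the angular uncertainty of a Bragg vector scales inversely with its
#' length, so very short vectors form poorly determined observed triples,
#' while vectors at the edge of the reference resolution range risk having
#' no table entry at all), then by peak index; the order is fully
#' deterministic.
#'
#' @param peaks data frame with columns \code{intensity} and \code{snr}.
#' @param params an \code{\link{indexer_params}}.
#' @param lengths reciprocal-vector lengths of the peaks
#'   (\eqn{\mathrm{\AA}^{-1}}); required for the resolution key.
#' @param preferred_length target length (\eqn{\mathrm{\AA}^{-1}}) for
#'   tie-breaking; \code{NULL} (default) falls back to plain peak-index
#'   tie-breaks.
#' @return Data frame with columns \code{i}, \code{j} (row indices into
#'   \code{peaks}) in rank order.
#' @export
select_peak_pairs <- function(peaks, params = indexer_params(),
                              lengths = NULL, preferred_length = NULL) {
  n <- nrow(peaks)
  if (n < 2L) stop("not indexable: need at least 2 peaks to form a pair")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  if (params$sort_key == "resolution") {
    if (is.null(lengths))
      stop("resolution sort requires reciprocal-vector lengths")
    d <- 1 / lengths
    ord <- order(d[i] + d[j], i, j)
  } else {
    key <- peaks[[params$sort_key]]
    tie <- if (is.null(lengths) || is.null(preferred_length)) rep(0, length(i))
           else abs(lengths[i] - preferred_length) +
                abs(lengths[j] - preferred_length)
    ord <- order(-(key[i] + key[j]), tie, i, j)
  }
  ord <- ord[seq_len(min(params$n_pairs, length(ord)))]
  data.frame(i = i[ord], j = j[ord])
}

#' Rotation from a matched peak pair
#'
#' Given two observed reciprocal vectors and the Miller-index pair they are
#' assumed to correspond to, constructs the proper rotation that carries the
#' reference vectors \eqn{B h} onto the observed ones: right-handed
#' orthonormal triads are built over each pair and
#' \eqn{U = T_{obs} T_{ref}'}. \eqn{\det U = +1} by construction.
#'
#' @param q_pair 2 x 3 matrix of observed reciprocal vectors.
#' @param hkl_pair 2 x 3 matrix of integer Miller triples, row k assigned to
#'   observed vector k.
#' @param cell a \code{\link{unit_cell}}.
#' @return 3 x 3 proper rotation matrix.
#' @export
solve_rotation <- function(q_pair, hkl_pair, cell) {
  q_pair <- matrix(as.numeric(q_pair), 2L, 3L)
  r <- matrix(as.numeric(hkl_pair), 2L, 3L) %*% t(cell$B)
  T_obs <- .unit_triad(q_pair[1L, ], q_pair[2L, ])
  T_ref <- .unit_triad(r[1L, ], r[2L, ])
  T_obs %*% t(T_ref)
}

#' Score an orientation against observed reciprocal vectors
#'
#' For each peak the fractional Miller index \eqn{h_f = (U B)^{-1} q} is
#' computed; the residual is the largest component distance to the nearest
#' integers and the peak is matched when it does not exceed \code{delta}.
#' The score S is the matched-peak count.
#'
#' @param U 3 x 3 proper rotation.
#' @param cell a \code{\link{unit_cell}}.
#' @param q n x 3 matrix of observed reciprocal vectors.
#' @param delta matching threshold on the fractional-index residual.
#' @return List with \code{score} (integer S) and \code{records}, a data
#'   frame of per-peak fractional indices, nearest integer indices,
#'   residuals and match flags.
#' @export
score_solution <- function(U, cell, q, delta = 0.25) {
  if (!.is_rotation(U, tol = 1e-6))
    stop("U must be a proper rotation matrix")
  q <- matrix(as.numeric(q), ncol = 3L)
  frac <- t(solve(U %*% cell$B, t(q)))
  hint <- .round_half_away(frac)
  dev <- abs(frac - hint)
  residual <- pmax(dev[, 1L], dev[, 2L], dev[, 3L])
  matched <- residual <= delta
  list(score = sum(matched),
       records = data.frame(peak = seq_len(nrow(q)),
                            hf1 = frac[, 1L], hf2 = frac[, 2L], hf3 = frac[, 3L],
                            h = hint[, 1L], k = hint[, 2L], l = hint[, 3L],
                            residual = residual, matched = matched))
}

# ---- internal candidate search -------------------------------------------

# residual matrix helper: FR is a (3 n_c) x m stack of fractional indices;
# returns the n_c x m matrix of max-component deviations
.stack_residuals <- function(FR) {
  D <- abs(FR - .round_half_away(FR))
  i1 <- seq.int(1L, nrow(D), by = 3L)
  pmax(D[i1, , drop = FALSE], D[i1 + 1L, , drop = FALSE],
       D[i1 + 2L, , drop = FALSE])
}

# deterministic, permutation-invariant resolution-stratified subset of peaks
.prescore_subset <- function(len, m) {
  n <- length(len)
  if (n <= m) return(seq_len(n))
  ord <- order(len, seq_len(n))
  ord[unique(round(seq(1, n, length.out = m)))]
}

# generate, prescore and shortlist rotation candidates for the peak pairs
# selected under one colour conversion. qlist: list of per-colour q matrices
# used for scoring (length 1 = monochromatic, 2 = two-colour). Because the
# true colour of a seed pair is unknown, every selected pair is matched
# against the table under EVERY wavelength hypothesis whose converted
# lengths fall inside the table's range. Returns a list of candidate
# records in deterministic order.
.collect_candidates <- function(sel_colour, qlist, peaks, table, params,
                                subset_idx) {
  q_sel <- qlist[[sel_colour]]
  len_sel <- .row_norms(q_sel)
  tol <- params$tol_len
  seed <- which(len_sel >= table$len_range[1L] - tol &
                  len_sel <= table$len_range[2L] + tol)
  if (length(seed) < 2L) return(list())
  prs <- select_peak_pairs(peaks[seed, , drop = FALSE], params,
                           lengths = len_sel[seed],
                           preferred_length = 0.85 * table$len_range[2L])
  Binv <- table$cell$Binv
  ms <- table$min_angle_sep
  m <- length(subset_idx)
  Ysub <- lapply(qlist, function(qq) t(qq[subset_idx, , drop = FALSE]))
  out <- list()
  for (r in seq_len(nrow(prs))) {
    pi <- seed[prs$i[r]]; pj <- seed[prs$j[r]]
    for (hyp in seq_along(qlist)) {      # wavelength hypothesis of the pair
      v1 <- qlist[[hyp]][pi, ]; v2 <- qlist[[hyp]][pj, ]
      l1 <- sqrt(sum(v1 * v1)); l2 <- sqrt(sum(v2 * v2))
      if (min(l1, l2) < table$len_range[1L] - tol ||
          max(l1, l2) > table$len_range[2L] + tol) next
      ang <- .vec_angle(v1, v2)
      if (ang < ms || ang > 180 - ms) next
      cand <- .candidate_pairs(table, l1, l2, ang,
                               params$tol_len, params$tol_angle)
      nc <- nrow(cand)
      if (!nc) next
      T_obs <- .unit_triad(v1, v2)
      tri <- .triad_stack(table$q[cand$ia, , drop = FALSE],
                          table$q[cand$ib, , drop = FALSE])
      A <- .block_stack(Binv, tri)                  # stack of Binv %*% T_ref
      Y <- crossprod(T_obs, do.call(cbind, Ysub))   # T_obs' q, all colours
      R <- .stack_residuals(A %*% Y)
      if (length(qlist) == 2L)
        R <- pmin(R[, seq_len(m), drop = FALSE],
                  R[, m + seq_len(m), drop = FALSE])
      M <- R <= params$delta
      S <- rowSums(M)
      rs <- rowSums(R * M)
      keep <- order(-S, rs, seq_len(nc))[seq_len(min(params$shortlist, nc))]
      for (k in keep) {
        T_ref <- .unit_triad(table$q[cand$ia[k], ], table$q[cand$ib[k], ])
        out[[length(out) + 1L]] <- list(
          U = T_obs %*% t(T_ref),
          colour = hyp, pair_rank = r,
          seed_pair = c(pi, pj),
          hkl_pair = rbind(table$hkl[cand$ia[k], ], table$hkl[cand$ib[k], ]))
      }
    }
  }
  out
}

# full scoring of a candidate list over all peaks and all colours; returns
# per-candidate S, matched-residual sums, and per-colour residual matrices
# for the winner
.full_score <- function(cands, qlist, cell, delta) {
  k <- length(cands)
  n <- nrow(qlist[[1L]])
  Binv <- cell$Binv
  A <- matrix(0, 3L * k, 3L)
  for (c in seq_len(k))
    A[(3L * c - 2L):(3L * c), ] <- Binv %*% t(cands[[c]]$U)
  Y <- do.call(cbind, lapply(qlist, t))
  R <- .stack_residuals(A %*% Y)
  if (length(qlist) == 2L) {
    R1 <- R[, seq_len(n), drop = FALSE]
    R2 <- R[, n + seq_len(n), drop = FALSE]
    Rmin <- pmin(R1, R2)
  } else {
    R1 <- Rmin <- R
    R2 <- NULL
  }
  M <- Rmin <= delta
  list(S = rowSums(M), resid_sum = rowSums(Rmin * M), R1 = R1, R2 = R2)
}

# shared engine behind the mono and two-colour indexers
.index_core <- function(qlist, peaks, table, params, two_colour) {
  n <- nrow(qlist[[1L]])
  if (n < 2L) return(NULL)
  min_score <- .min_score(params, n)
  subset_idx <- .prescore_subset(.row_norms(qlist[[1L]]),
                                 params$prescore_peaks)
  cands <- list()
  for (col in seq_along(qlist))
    cands <- c(cands, .collect_candidates(col, qlist, peaks, table,
                                          params, subset_idx))
  if (!length(cands)) return(NULL)
  fs <- .full_score(cands, qlist, table$cell, params$delta)
  best <- order(-fs$S, fs$resid_sum, seq_along(cands))[1L]
  if (fs$S[best] < min_score) return(NULL)
  list(cand = cands[[best]], S = fs$S[best],
       R1 = fs$R1[best, ], R2 = if (two_colour) fs$R2[best, ])
}

#' Monochromatic reference-table indexing
#'
#' Single-wavelength engine: ranks peak pairs, matches their observed
#' triples against the reference table, solves a rotation for every matched
#' entry (both vector-to-index assignments arise naturally from the ordered
#' query), scores each candidate by the matched-peak count S and returns
#' the best solution -- ties broken by the smaller summed residual over
#' matched peaks, then by earlier candidate rank. Returns \code{NULL} when
#' fewer than 2 peaks are given, no candidate exists, or the best S falls
#' below \code{min_score}.
#'
#' @param x a \code{\link{peak_list}} (requires \code{geometry} and
#'   \code{wavelength}) or an n x 3 matrix of reciprocal vectors.
#' @param table a \code{\link{reference_table}}.
#' @param params an \code{\link{indexer_params}}.
#' @param geometry a \code{\link{detector_geometry}} (peak-list input only).
#' @param wavelength wavelength in Angstroms (peak-list input only).
#' @return An \code{"index_solution"} object or \code{NULL}: rotation
#'   \code{U}, \code{score}, per-peak \code{records}, and the seed pair that
#'   generated the winning rotation.
#' @export
index_monochromatic <- function(x, table, params = indexer_params(),
                                geometry = NULL, wavelength = NULL) {
  if (is.matrix(x)) {
    q <- x
    peaks <- data.frame(fs = NA_real_, ss = NA_real_, intensity = 1,
                        snr = 1)[rep(1L, nrow(q)), , drop = FALSE]
  } else {
    stopifnot(!is.null(geometry), !is.null(wavelength))
    peaks <- x
    q <- pixel_to_q(peaks$fs, peaks$ss, geometry, wavelength)
  }
  res <- .index_core(list(q), peaks, table, params, two_colour = FALSE)
  if (is.null(res)) return(NULL)
  sc <- score_solution(res$cand$U, table$cell, q, params$delta)
  structure(list(rotation = res$cand$U, score = sc$score,
                 records = sc$records,
                 seed_pair = res$cand$seed_pair,
                 seed_hkl = res$cand$hkl_pair,
                 cell = table$cell, params = params,
                 n_peaks = nrow(q)),
            class = "index_solution")
}

#' @export
print.index_solution <- function(x, ...) {
  cat(sprintf("Indexing solution: S = %d / %d peaks matched (delta = %g)\n",
              x$score, x$n_peaks, x$params$delta))
  cat("Rotation U:\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' @export
coef.index_solution <- function(object, ...) object$rotation

#' @export
residuals.index_solution <- function(object, ...) object$records$residual
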