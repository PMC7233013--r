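#' Enumerate reference reflections of a unit cell
#'
#' Lists every integer Miller triple (excluding the origin) whose resolution
#' \eqn{d = 1/|B h|} is at least \code{d_min}. The index bound along each
#' axis follows from \eqn{|h| = |\vec{a} \cdot q| \le a / d_{min}} (and
#' likewise for k, l), so no admissible triple is missed for any triclinic
#' cell.
#'
#' @param cell a \code{\link{unit_cell}}.
#' @param d_min resolution cutoff in Angstroms (> 0).
#' @param max_reflections guard against absurdly small cutoffs; exceeding it
#'   raises a size-limit error.
#' @return Data frame with columns \code{h}, \code{k}, \code{l}, \code{qx},
#'   \code{qy}, \code{qz}, \code{length} (\eqn{\mathrm{\AA}^{-1}}) and
#'   \code{resolution} (Angstroms), sorted by increasing length.
#' @examples
#' nrow(enumerate_reflections(unit_cell(10, 10, 10), d_min = 5))  # 32
#' @export
enumerate_reflections <- function(cell, d_min, max_reflections = 1e6) {
  stopifnot(inherits(cell, "unit_cell"), d_min > 0)
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  n_grid <- (2 * hmax + 1) * (2 * kmax + 1) * (2 * lmax + 1)
  if (n_grid > 20 * max_reflections)
    stop("size limit: d_min = ", d_min,
         " A would enumerate more than the configured reflection cap")
  hkl <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  if (nrow(hkl) == 0L)
    return(data.frame(h = integer(), k = integer(), l = integer(),
                      qx = numeric(), qy = numeric(), qz = numeric(),
                      length = numeric(), resolution = numeric()))
  q <- hkl %*% t(cell$B)
  len <- .row_norms(q)
  keep <- len <= (1 / d_min) * (1 + 1e-12)
  hkl <- hkl[keep, , drop = FALSE]
  q <- q[keep, , drop = FALSE]
  len <- len[keep]
  if (length(len) > max_reflections)
    stop("size limit: ", length(len), " reflections exceed the cap of ",
         max_reflections)
  ord <- order(len, hkl[, 1L], hkl[, 2L], hkl[, 3L])
  data.frame(h = hkl[ord, 1L], k = hkl[ord, 2L], l = hkl[ord, 3L],
             qx = q[ord, 1L], qy = q[ord, 2L], qz = q[ord, 3L],
             length = len[ord], resolution = 1 / len[ord],
             row.names = NULL)
}

#' Build the orientation-independent reference pair table
#'
#' Each unordered pair of reference reflections is characterized by an
#' orientation-invariant triple: the two reciprocal-vector lengths (in
#' canonical order, shorter first) and the angle between the vectors.
#' Observed peak pairs are matched against these triples to obtain candidate
#' Miller-index assignments. Friedel mates (+hkl and -hkl) are both kept
#' (space group P1, no symmetry reduction), so the rotation solver sees all
#' sign combinations. Near-collinear pairs (angle within
#' \code{min_angle_sep} of 0 or 180 degrees) carry no orientation
#' information and are excluded.
#'
#' The table holds the reflection list sorted by vector length and answers
#' tolerance queries by a length-window binary search followed by an exact
#' angle filter; this is equivalent to a linear scan over all materialized
#' pairs (see \code{\link{table_entries}}) without ever storing the
#' quadratic pair list.
#'
#' @param cell a \code{\link{unit_cell}}.
#' @param d_min resolution cutoff in Angstroms for the reference reflections
#'   (default 5).
#' @param min_angle_sep minimal angular separation from collinearity,
#'   degrees (default 10).
#' @param max_entries cap on the number of pair entries that may be
#'   materialized by \code{\link{table_entries}} (default 5e6).
#' @param reflections optional pre-computed reflection list (as returned by
#'   \code{\link{enumerate_reflections}}); enumerated from the cell if NULL.
#' @return Object of class \code{"reference_table"}.
#' @examples
#' tab <- reference_table(unit_cell(10, 10, 10), d_min = 5)
#' tab
#' @export
reference_table <- function(cell, d_min = 5, min_angle_sep = 10,
                            max_entries = 5e6, reflections = NULL) {
  stopifnot(inherits(cell, "unit_cell"), d_min > 0,
            min_angle_sep >= 0, min_angle_sep < 90)
  if (is.null(reflections))
    reflections <- enumerate_reflections(cell, d_min)
  if (nrow(reflections) < 2L)
    stop("table too small: need at least 2 reference reflections")
  ord <- order(reflections$length)
  reflections <- reflections[ord, , drop = FALSE]
  structure(list(cell = cell, d_min = d_min,
                 min_angle_sep = min_angle_sep, max_entries = max_entries,
                 hkl = unname(as.matrix(reflections[, c("h", "k", "l")])),
                 q = unname(as.matrix(reflections[, c("qx", "qy", "qz")])),
                 length = reflections$length,
                 len_range = range(reflections$length)),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Reference table: %d reflections to %.3g A (lengths %.4f-%.4f 1/A)\n",
              nrow(x$hkl), x$d_min, x$len_range[1], x$len_range[2]))
  cat(sprintf("Pair entries (implicit): <= %d; min angular separation %.1f deg\n",
              choose(nrow(x$hkl), 2L), x$min_angle_sep))
  invisible(x)
}

# indices into the sorted length vector within [val - tol, val + tol]
.len_window <- function(len, val, tol) {
  lo <- findInterval(val - tol, len, left.open = TRUE) + 1L
  hi <- findInterval(val + tol, len)
  if (hi < lo) integer() else lo:hi
}

# ordered candidate reflection pairs for an observed pair: ia is matched to
# the first observed vector (length l1), ib to the second (length l2);
# exact angle filter plus the table's collinearity exclusion
.candidate_pairs <- function(table, l1, l2, angle, tol_len, tol_angle) {
  ia <- .len_window(table$length, l1, tol_len)
  ib <- .len_window(table$length, l2, tol_len)
  empty <- data.frame(ia = integer(), ib = integer(), angle = numeric())
  if (!length(ia) || !length(ib)) return(empty)
  Qa <- table$q[ia, , drop = FALSE]
  Qb <- table$q[ib, , drop = FALSE]
  ca <- (Qa %*% t(Qb)) / outer(table$length[ia], table$length[ib])
  ang <- .deg(acos(.clamp(ca, -1, 1)))
  ms <- table$min_angle_sep
  # exactly collinear pairs are always excluded, whatever min_angle_sep
  keep <- abs(ang - angle) <= tol_angle & ang >= ms & ang <= 180 - ms &
    ang > 1e-4 & ang < 180 - 1e-4 & outer(ia, ib, `!=`)
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(ia = ia[idx[, 1L]], ib = ib[idx[, 2L]],
                    angle = ang[idx])
  out[order(out$ia, out$ib), , drop = FALSE]
}

#' Query the reference table with an observed triple
#'
#' Returns exactly the pair entries whose canonical triple matches the
#' observed one within the given tolerances:
#' \eqn{|len_a - obs_a| \le tol_{len}}, \eqn{|len_b - obs_b| \le tol_{len}}
#' and \eqn{|angle - obs| \le tol_{angle}}. An empty result is a valid
#' outcome. Equivalent to a linear scan over \code{\link{table_entries}}.
#'
#' @param table a \code{\link{reference_table}}.
#' @param len_a,len_b observed reciprocal-vector lengths in canonical order
#'   (\code{len_a <= len_b}), \eqn{\mathrm{\AA}^{-1}}.
#' @param angle observed inter-vector angle in degrees.
#' @param tol_len length tolerance in \eqn{\mathrm{\AA}^{-1}} (default
#'   0.0025).
#' @param tol_angle angle tolerance in degrees (default 1).
#' @return Data frame with one row per matching entry: \code{ia}, \code{ib}
#'   (row indices into the table's reflection list, \code{ia} carrying the
#'   shorter length), \code{len_a}, \code{len_b}, \code{angle},
#'   \code{ha,ka,la,hb,kb,lb}.
#' @export
query_table <- function(table, len_a, len_b, angle,
                        tol_len = 0.0025, tol_angle = 1) {
  stopifnot(inherits(table, "reference_table"), len_a <= len_b,
            tol_len >= 0, tol_angle >= 0)
  cand <- .candidate_pairs(table, len_a, len_b, angle, tol_len, tol_angle)
  if (nrow(cand)) {
    # canonicalize: entry lengths are (min, max); a candidate matches if the
    # shorter member is within tol of len_a and the longer within tol of len_b
    la <- table$length[cand$ia]; lb <- table$length[cand$ib]
    lmin <- pmin(la, lb); lmax <- pmax(la, lb)
    keep <- abs(lmin - len_a) <= tol_len & abs(lmax - len_b) <= tol_len
    cand <- cand[keep, , drop = FALSE]
    swap <- table$length[cand$ia] > table$length[cand$ib] |
      (table$length[cand$ia] == table$length[cand$ib] & cand$ia > cand$ib)
    ia <- ifelse(swap, cand$ib, cand$ia)
    ib <- ifelse(swap, cand$ia, cand$ib)
    dup <- duplicated(cbind(ia, ib))
    ia <- ia[!dup]; ib <- ib[!dup]
  } else {
    ia <- ib <- integer()
  }
  ord <- order(ia, ib)
  ia <- ia[ord]; ib <- ib[ord]
  data.frame(ia = ia, ib = ib,
             len_a = table$length[ia], len_b = table$length[ib],
             angle = if (length(ia))
               apply(cbind(ia, ib), 1L, function(p)
                 .vec_angle(table$q[p[1L], ], table$q[p[2L], ]))
             else numeric(),
             ha = table$hkl[ia, 1L], ka = table$hkl[ia, 2L], la = table$hkl[ia, 3L],
             hb = table$hkl[ib, 1L], kb = table$hkl[ib, 2L], lb = table$hkl[ib, 3L],
             row.names = NULL)
}

#' Materialize the full pair-entry list of a reference table
#'
#' Generates every unordered reflection pair with angle inside the
#' collinearity band, in canonical (shorter length first) order. Intended
#' for small tables, oracle checks and serialization; refuses to build more
#' than \code{max_entries} rows.
#'
#' @param table a \code{\link{reference_table}}.
#' @param max_entries override of the table's materialization cap.
#' @return Data frame with columns \code{ia}, \code{ib}, \code{len_a},
#'   \code{len_b}, \code{angle}, and the two Miller triples.
#' @export
table_entries <- function(table, max_entries = table$max_entries) {
  n <- nrow(table$hkl)
  if (choose(n, 2) > max_entries)
    stop("size limit: ", format(choose(n, 2), big.mark = ","),
         " pair entries exceed the cap of ", format(max_entries, big.mark = ","),
         "; use tolerance queries instead of materializing the table")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  ca <- rowSums(table$q[i, , drop = FALSE] * table$q[j, , drop = FALSE]) /
    (table$length[i] * table$length[j])
  ang <- .deg(acos(.clamp(ca, -1, 1)))
  ms <- table$min_angle_sep
  keep <- ang >= ms & ang <= 180 - ms & ang > 1e-4 & ang < 180 - 1e-4
  i <- i[keep]; j <- j[keep]; ang <- ang[keep]
  # canonical order: i always carries the shorter length (i <= j holds by
  # construction because reflections are sorted by length)
  data.frame(ia = i, ib = j,
             len_a = table$length[i], len_b = table$length[j], angle = ang,
             ha = table$hkl[i, 1L], ka = table$hkl[i, 2L], la = table$hkl[i, 3L],
             hb = table$hkl[j, 1L], kb = table$hkl[j, 2L], lb = table$hkl[j, 3L],
             row.names = NULL)
}

#' Write / read a reference-table cache
#'
#' Plain-text TSV cache of the reflection list with the cell parameters and
#' cutoffs in a header comment, so a table can be rebuilt without
#' re-enumeration and verified against the generating configuration.
#'
#' @param table a \code{\link{reference_table}}.
#' @param path file path.
#' @return \code{read_table_cache} returns the restored
#'   \code{\link{reference_table}}.
#' @export
write_table_cache <- function(table, path) {
  hdr <- sprintf("# tcindex reference table\n# cell\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g\n# d_min\t%.10g\n# min_angle_sep\t%.10g",
                 table$cell$a, table$cell$b, table$cell$c,
                 table$cell$alpha, table$cell$beta, table$cell$gamma,
                 table$d_min, table$min_angle_sep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(h = table$hkl[, 1L], k = table$hkl[, 2L], l = table$hkl[, 3L],
                   qx = table$q[, 1L], qy = table$q[, 2L], qz = table$q[, 3L],
                   length = table$length)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_cache
#' @export
read_table_cache <- function(path) {
  lines <- readLines(path, n = 4L)
  if (!startsWith(lines[1L], "# tcindex reference table"))
    stop("not a tcindex table cache: ", path)
  cellpar <- as.numeric(strsplit(lines[2L], "\t")[[1L]][-1L])
  d_min <- as.numeric(strsplit(lines[3L], "\t")[[1L]][2L])
  msep <- as.numeric(strsplit(lines[4L], "\t")[[1L]][2L])
  df <- utils::read.delim(path, comment.char = "#")
  cell <- unit_cell(cellpar[1], cellpar[2], cellpar[3],
                    cellpar[4], cellpar[5], cellpar[6])
  refl <- data.frame(h = df$h, k = df$k, l = df$l,
                     qx = df$qx, qy = df$qy, qz = df$qz,
                     length = df$length, resolution = 1 / df$length)
  reference_table(cell, d_min = d_min, min_angle_sep = msep,
                  reflections = refl)
}
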