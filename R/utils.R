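# internal numerical helpers

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

.row_norms <- function(m) sqrt(rowSums(m * m))

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.row_cross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

# round half away from zero; pinned for determinism even though residuals
# below 0.25 make the half-integer case measure-zero
.round_half_away <- function(x) trunc(x + 0.5 * sign(x))

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_rotation <- function(U, tol = 1e-9) {
  is.matrix(U) && all(dim(U) == c(3L, 3L)) && all(is.finite(U)) &&
    max(abs(crossprod(U) - diag(3))) < tol && abs(det(U) - 1) < tol
}

# angle between two 3-vectors, degrees in [0, 180]
.vec_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  .deg(acos(.clamp(ca, -1, 1)))
}

# proper rotation from an axis-angle 3-vector (Rodrigues); |w| is the angle
# in radians, w/|w| the axis
.axis_angle_matrix <- function(w) {
  th <- sqrt(sum(w * w))
  if (th < 1e-15) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3L], -k[2L],
                -k[3L], 0, k[1L],
                k[2L], -k[1L], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# right-handed orthonormal triad (columns) spanned by two non-collinear
# vectors: e1 along v1, e3 along v1 x v2, e2 completing the frame
.unit_triad <- function(v1, v2) {
  e1 <- v1 / sqrt(sum(v1 * v1))
  c3 <- .cross3(v1, v2)
  n3 <- sqrt(sum(c3 * c3))
  if (n3 < 1e-12 * sqrt(sum(v1 * v1)) * sqrt(sum(v2 * v2)))
    stop("degenerate pair: vectors are collinear")
  e3 <- c3 / n3
  e2 <- .cross3(e3, e1)
  cbind(e1, e2, e3, deparse.level = 0)
}

# vectorized triads for n vector pairs; returns n x 3 matrices E1, E2, E3
.triad_stack <- function(V1, V2) {
  E1 <- V1 / .row_norms(V1)
  C3 <- .row_cross(V1, V2)
  E3 <- C3 / .row_norms(C3)
  E2 <- .row_cross(E3, E1)
  list(E1 = E1, E2 = E2, E3 = E3)
}

# stack of 3x3 blocks M %*% T_c for every triad c, as a (3n) x 3 matrix;
# block c occupies rows 3c-2 .. 3c
.block_stack <- function(M, tri) {
  X1 <- tri$E1 %*% t(M)          # row c = (M e1_c)'
  X2 <- tri$E2 %*% t(M)
  X3 <- tri$E3 %*% t(M)
  n <- nrow(X1)
  arr <- array(c(X1, X2, X3), dim = c(n, 3L, 3L))  # arr[c, r, j] = Xj[c, r]
  matrix(aperm(arr, c(2L, 1L, 3L)), nrow = 3L * n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
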