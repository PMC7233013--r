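# shared fixtures, built once per test run

toy_cell <- unit_cell(10, 10, 10)                       # cubic toy lattice
tri_cell <- unit_cell(64.3, 72.0, 89.2, 110.6, 107.5, 85.8)

toy_table <- reference_table(toy_cell, d_min = 5)       # 32 reflections

# low-resolution variant of the full problem: same cell and geometry, both
# the simulation and the table cut at 8 A, which keeps unit tests fast
small_table <- reference_table(tri_cell, d_min = 8)
small_config <- simulation_config(cell = tri_cell, d_min = 8)

# exact lattice peaks of the toy cell: q = U B hkl for a reflection subset,
# guaranteed to contain at least one pair inside the table's angular band
toy_lattice_pattern <- function(n_peaks, U = diag(3), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    pick <- sample(nrow(toy_table$hkl), n_peaks)
    q <- toy_table$hkl[pick, , drop = FALSE] %*% t(toy_cell$B) %*% t(U)
    angs <- combn(n_peaks, 2, function(p) {
      v1 <- q[p[1], ]; v2 <- q[p[2], ]
      acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    })
    if (any(angs > toy_table$min_angle_sep + 0.5 &
            angs < 180 - toy_table$min_angle_sep - 0.5)) break
  }
  list(q = q, hkl = toy_table$hkl[pick, , drop = FALSE])
}

# exact lattice peaks of the triclinic cell (no lattice symmetry, so the
# indexing solution is unique): q = U B hkl for a reflection subset
tri_lattice_pattern <- function(n_peaks, U = diag(3), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- sample(nrow(small_table$hkl), n_peaks)
  list(q = small_table$hkl[pick, , drop = FALSE] %*% t(tri_cell$B) %*% t(U),
       hkl = small_table$hkl[pick, , drop = FALSE])
}

expect_rotation <- function(U, tol = 1e-9) {
  expect_lt(max(abs(crossprod(U) - diag(3))), tol)
  expect_equal(det(U), 1, tolerance = tol)
}
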