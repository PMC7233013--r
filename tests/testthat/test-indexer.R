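test_that("peak pairs are ranked by the summed key with deterministic ties", {
  pk <- peak_list(1:3, 1:3, snr = c(9, 5, 1))
  expect_equal(nrow(select_peak_pairs(pk, indexer_params(n_pairs = 10))), 3L)
  top <- select_peak_pairs(pk, indexer_params(n_pairs = 1))
  expect_equal(c(top$i, top$j), c(1L, 2L))

  # exhaustive-sort oracle on 20 random peaks with distinct keys
  set.seed(6)
  pk <- peak_list(runif(20), runif(20), intensity = sample(1000, 20),
                  snr = sample(1000, 20))
  for (key in c("snr", "intensity")) {
    got <- select_peak_pairs(pk, indexer_params(n_pairs = 190, sort_key = key))
    all_pairs <- t(combn(20, 2))
    val <- pk[[key]][all_pairs[, 1]] + pk[[key]][all_pairs[, 2]]
    want <- all_pairs[order(-val, all_pairs[, 1], all_pairs[, 2]), ]
    expect_equal(as.matrix(got), want, ignore_attr = TRUE)
  }
  # resolution key: best (smallest summed d-spacing) first
  len <- runif(20, 0.05, 0.3)
  got <- select_peak_pairs(pk, indexer_params(n_pairs = 190,
                                              sort_key = "resolution"),
                           lengths = len)
  d <- 1 / len
  all_pairs <- t(combn(20, 2))
  want <- all_pairs[order(d[all_pairs[, 1]] + d[all_pairs[, 2]],
                          all_pairs[, 1], all_pairs[, 2]), ]
  expect_equal(as.matrix(got), want, ignore_attr = TRUE)

  expect_error(select_peak_pairs(pk[1, ], indexer_params()), "indexable")
})

test_that("solve_rotation recovers known orientations from a vector pair", {
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0))
  q0 <- hkl %*% t(toy_cell$B)

  expect_equal(solve_rotation(q0, hkl, toy_cell), diag(3), tolerance = 1e-10)

  set.seed(7)
  for (i in 1:20) {
    R <- random_orientation()
    hkl2 <- rbind(c(2, 1, 0), c(0, -1, 1))
    U <- solve_rotation(hkl2 %*% t(toy_cell$B) %*% t(R), hkl2, toy_cell)
    expect_lt(max(abs(U - R)), 1e-10)
    expect_rotation(U)
  }

  # 0.5 degree of angular noise on one observed vector: recovery stays
  # within about a degree (sanity bound, not exact)
  R <- random_orientation()
  q_obs <- hkl %*% t(toy_cell$B) %*% t(R)
  tweak <- euler_to_matrix(c(0.5, 0, 0))
  q_obs[2, ] <- q_obs[2, ] %*% t(tweak)
  U <- solve_rotation(q_obs, hkl, toy_cell)
  expect_lt(orientation_error(U, R)$total, 2)

  expect_error(solve_rotation(rbind(c(0.1, 0, 0), c(0.2, 0, 0)),
                              rbind(c(1, 0, 0), c(2, 0, 0)), toy_cell),
               "collinear")
})

test_that("score_solution counts fractional-index matches", {
  set.seed(8)
  U <- random_orientation()
  pat <- toy_lattice_pattern(8, U)
  sc <- score_solution(U, toy_cell, pat$q, delta = 0.25)
  expect_equal(sc$score, 8L)
  expect_lt(max(sc$records$residual), 1e-10)
  expect_equal(as.matrix(sc$records[, c("h", "k", "l")]), pat$hkl,
               ignore_attr = TRUE)

  # threshold straddle at hkl_frac = (1.3, 0, 0)
  q13 <- t(toy_cell$B %*% c(1.3, 0, 0))
  expect_equal(score_solution(diag(3), toy_cell, q13, 0.25)$score, 0L)
  expect_equal(score_solution(diag(3), toy_cell, q13, 0.25)$records$residual,
               0.3)
  expect_equal(score_solution(diag(3), toy_cell, q13, 0.35)$score, 1L)

  # independent per-peak re-implementation oracle on random input
  U <- random_orientation()
  q <- matrix(runif(60, -0.2, 0.2), 20, 3)
  sc <- score_solution(U, toy_cell, q, 0.25)
  UBi <- solve(U %*% toy_cell$B)
  s_oracle <- 0L
  for (i in 1:20) {
    hf <- as.numeric(UBi %*% q[i, ])
    res <- max(abs(hf - round(hf)))
    if (res <= 0.25) s_oracle <- s_oracle + 1L
    expect_equal(sc$records$residual[i], res, tolerance = 1e-12)
  }
  expect_equal(sc$score, s_oracle)

  expect_error(score_solution(diag(2, 3), toy_cell, q13), "rotation")
})

test_that("S is non-decreasing in delta for a fixed rotation", {
  set.seed(9)
  U <- random_orientation()
  q <- matrix(runif(90, -0.2, 0.2), 30, 3)
  s <- vapply(seq(0.05, 0.5, by = 0.05),
              function(d) score_solution(U, toy_cell, q, d)$score, integer(1))
  expect_true(all(diff(s) >= 0))
})

test_that("the monochromatic indexer recovers triclinic lattice orientations", {
  params <- indexer_params(n_pairs = 30)

  # identity orientation, noise-free
  pat <- tri_lattice_pattern(8, diag(3), seed = 10)
  sol <- index_monochromatic(pat$q, small_table, params)
  expect_s3_class(sol, "index_solution")
  expect_equal(sol$score, 8L)
  expect_lt(orientation_error(sol$rotation, diag(3))$total, 1e-6)
  expect_rotation(sol$rotation)

  # known random orientations
  set.seed(11)
  for (i in 1:5) {
    U <- random_orientation()
    pat <- tri_lattice_pattern(7, U)
    sol <- index_monochromatic(pat$q, small_table, params)
    expect_equal(sol$score, 7L)
    expect_lt(orientation_error(sol$rotation, U)$total, 0.2)
  }

  expect_null(index_monochromatic(matrix(numeric(), 0, 3), toy_table, params))
})

test_that("random peaks without lattice structure are not indexed", {
  set.seed(12)
  repeat {   # draw vectors inside the table's length range
    q <- matrix(runif(24, -0.15, 0.15), 8, 3)
    len <- sqrt(rowSums(q^2))
    if (all(len > 0.08 & len < 0.21)) break
  }
  expect_null(index_monochromatic(q, toy_table, indexer_params(n_pairs = 10)))
})

test_that("peak order does not change the solution for distinct sort keys", {
  set.seed(13)
  U <- random_orientation()
  pat <- tri_lattice_pattern(8, U)
  pk <- peak_list(rep(NA_real_, 8), rep(NA_real_, 8), snr = sample(100, 8))

  index_q <- function(q, peaks, perm = seq_len(nrow(q))) {
    # mirror index_monochromatic's matrix entry but with real snr keys
    res <- tcindex:::.index_core(list(q[perm, ]), peaks[perm, ],
                                 small_table, indexer_params(n_pairs = 10),
                                 two_colour = FALSE)
    list(S = res$S, U = res$cand$U)
  }
  base <- index_q(pat$q, pk)
  for (i in 1:4) {
    perm <- sample(8)
    permuted <- index_q(pat$q, pk, perm)
    expect_equal(permuted$S, base$S)
    expect_equal(permuted$U, base$U, tolerance = 1e-12)
  }
})
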