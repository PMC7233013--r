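test_that("equal wavelengths degrade two-colour scoring to monochromatic", {
  set.seed(14)
  U <- random_orientation()
  pat <- simulate_pattern(small_config, U)
  q <- pixel_to_q(pat$peaks$fs, pat$peaks$ss, small_config$geometry,
                  small_config$beam$wavelengths[1])
  mono <- score_solution(U, tri_cell, q, 0.25)
  tc <- score_two_color(U, tri_cell, q, q, 0.25)
  expect_equal(tc$score, mono$score)
  expect_equal(tc$residual_1, mono$records$residual)
  expect_equal(tc$residual_2, mono$records$residual)
})

test_that("the true orientation matches every simulated peak under its colour", {
  set.seed(15)
  U <- random_orientation()
  pat <- simulate_pattern(small_config, U)
  q1 <- pixel_to_q(pat$peaks$fs, pat$peaks$ss, small_config$geometry,
                   small_config$beam$wavelengths[1])
  q2 <- pixel_to_q(pat$peaks$fs, pat$peaks$ss, small_config$geometry,
                   small_config$beam$wavelengths[2])
  sc <- score_two_color(U, tri_cell, q1, q2, 0.25)
  expect_equal(sc$score, nrow(pat$peaks))

  # whenever the two residuals are clearly separated, the smaller one sits
  # under the true colour
  res_true <- ifelse(pat$peaks$true_color == 1, sc$residual_1, sc$residual_2)
  res_other <- ifelse(pat$peaks$true_color == 1, sc$residual_2, sc$residual_1)
  clear <- abs(sc$residual_1 - sc$residual_2) > 0.05 & !pat$peaks$dual
  expect_true(all(res_true[clear] < res_other[clear]))

  # two-colour score dominance over both monochromatic scores
  for (i in 1:3) {
    V <- random_orientation()
    stc <- score_two_color(V, tri_cell, q1, q2, 0.25)$score
    expect_gte(stc, score_solution(V, tri_cell, q1, 0.25)$score)
    expect_gte(stc, score_solution(V, tri_cell, q2, 0.25)$score)
  }
})

test_that("colour probabilities are an inverse residual share", {
  a <- assign_color_probabilities(0, 0.2)
  expect_equal(c(a$p_1, a$p_2), c(1, 0))
  expect_equal(a$assigned_color, 1L)

  a <- assign_color_probabilities(0.1, 0.1)
  expect_equal(c(a$p_1, a$p_2), c(0.5, 0.5))
  expect_true(is.na(a$assigned_color))

  a <- assign_color_probabilities(0, 0)     # both exact: ambiguous
  expect_equal(c(a$p_1, a$p_2), c(0.5, 0.5))

  # unmatched peaks keep reported probabilities but no assignment
  a <- assign_color_probabilities(0.4, 0.3, delta = 0.25)
  expect_false(a$matched)
  expect_true(is.na(a$assigned_color))
  expect_equal(a$p_1 + a$p_2, 1)

  # normalization property on random residual pairs
  set.seed(16)
  r1 <- runif(200, 0, 0.5); r2 <- runif(200, 0, 0.5)
  a <- assign_color_probabilities(r1, r2)
  expect_equal(a$p_1 + a$p_2, rep(1, 200))
  expect_true(all((a$p_1 > 0.5) == (r1 < r2)))
  expect_error(assign_color_probabilities(0.7, 0.1), "0.5")
})

test_that("refinement recovers a perturbed orientation and never worsens", {
  set.seed(17)
  U_true <- random_orientation()
  # exact lattice targets under the two colours
  pick1 <- sample(nrow(small_table$hkl), 25)
  pick2 <- sample(nrow(small_table$hkl), 25)
  g1 <- small_table$hkl[pick1, ] %*% t(tri_cell$B) %*% t(U_true)
  g2 <- small_table$hkl[pick2, ] %*% t(tri_cell$B) %*% t(U_true)

  # already optimal: stays put with objective ~ 0
  ref <- refine_solution(U_true, tri_cell, g1, g2)
  expect_lt(max(abs(ref$U - U_true)), 1e-8)
  expect_lt(ref$objective, 1e-15)

  # 0.5 degree off: recovered well below 0.02 degrees
  U0 <- euler_to_matrix(c(0.3, -0.28, 0.2)) %*% U_true
  ref <- refine_solution(U0, tri_cell, g1, g2)
  expect_lt(orientation_error(ref$U, U_true)$total, 0.02)
  expect_lte(ref$objective, ref$objective0)
  expect_rotation(ref$U, tol = 1e-9)

  # optimizer contract on arbitrary input: objective never increases
  for (i in 1:5) {
    U0 <- random_orientation()
    q1 <- matrix(runif(30, -0.1, 0.1), 10, 3)
    ref <- refine_solution(U0, tri_cell, q1)
    expect_lte(ref$objective, ref$objective0)
    expect_rotation(ref$U, tol = 1e-9)
  }

  # fewer than 3 peaks: returned unchanged, flagged
  ref <- refine_solution(U_true, tri_cell, g1[1:2, ], g2[0, , drop = FALSE])
  expect_true(ref$reverted)
  expect_identical(ref$U, U_true)
})

test_that("two-colour indexing solves mixed patterns end to end", {
  set.seed(18)
  U <- random_orientation()
  pat <- simulate_pattern(small_config, U)
  sol <- index_two_color(pat$peaks, small_table, small_config$geometry,
                         small_config$beam)
  expect_s3_class(sol, "tc_solution")
  expect_equal(sol$score, nrow(pat$peaks))
  expect_lt(orientation_error(sol$rotation, U)$total, 0.5)
  expect_rotation(sol$rotation)
  expect_lte(sol$refinement$objective, sol$refinement$objective0)

  # groups are disjoint and only contain matched, confidently assigned peaks
  expect_length(intersect(sol$group_1, sol$group_2), 0)
  asg <- sol$assignments
  expect_equal(sol$score, sum(pmin(asg$residual_1, asg$residual_2) <= 0.25))
  expect_equal(asg$p_1 + asg$p_2, rep(1, nrow(asg)))

  # colour recovery for unambiguous peaks
  clear <- !pat$peaks$dual & abs(asg$residual_1 - asg$residual_2) > 0.05 &
    !is.na(asg$assigned_color)
  expect_true(all(asg$assigned_color[clear] == pat$peaks$true_color[clear]))

  # solution methods
  expect_output(print(sol), "matched")
  expect_identical(coef(sol), sol$rotation)
  expect_equal(residuals(sol), pmin(asg$residual_1, asg$residual_2))
  expect_s3_class(summary(sol), "summary.tc_solution")
  pred <- predict(sol, d_min = 8)
  expect_true(all(c("fs", "ss", "color") %in% names(pred)))
})

test_that("patterns with a single colour still index; other group stays small", {
  set.seed(19)
  U <- random_orientation()
  pat <- simulate_pattern(small_config, U)
  only1 <- pat$peaks[pat$peaks$true_color == 1, ]
  sol <- index_two_color(only1, small_table, small_config$geometry,
                         small_config$beam)
  expect_s3_class(sol, "tc_solution")
  expect_lt(orientation_error(sol$rotation, U)$total, 0.5)
  expect_lt(length(sol$group_2), 0.1 * nrow(only1))
})

test_that("equal energies still index (degenerate two-colour mode)", {
  set.seed(20)
  U <- random_orientation()
  beam99 <- beam_setup(c(9, 9))
  cfg <- simulation_config(cell = tri_cell, d_min = 8, beam = beam99)
  pat <- simulate_pattern(cfg, U)
  # identical spheres register every spot under both colours; keep colour 1
  only1 <- pat$peaks[pat$peaks$true_color == 1, ]
  sol <- index_two_color(only1, small_table, cfg$geometry, beam99)
  expect_s3_class(sol, "tc_solution")
  expect_equal(sol$score, nrow(only1))
  expect_lt(orientation_error(sol$rotation, U)$total, 0.5)
})
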