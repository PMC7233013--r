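# independent brute-force enumeration over a generous index cube, with the
# reciprocal metric computed from the closed-form triclinic formulas
brute_count_reflections <- function(a, b, c, al, be, ga, d_min, span) {
  ca <- cospi(al / 180); cb <- cospi(be / 180); cg <- cospi(ga / 180)
  sa <- sinpi(al / 180); sb <- sinpi(be / 180); sg <- sinpi(ga / 180)
  V <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  as_ <- b * c * sa / V; bs_ <- a * c * sb / V; cs_ <- a * b * sg / V
  G <- matrix(c(as_^2, as_ * bs_ * (ca * cb - cg) / (sa * sb),
                as_ * cs_ * (ca * cg - cb) / (sa * sg),
                as_ * bs_ * (ca * cb - cg) / (sa * sb), bs_^2,
                bs_ * cs_ * (cb * cg - ca) / (sb * sg),
                as_ * cs_ * (ca * cg - cb) / (sa * sg),
                bs_ * cs_ * (cb * cg - ca) / (sb * sg), cs_^2), 3, 3)
  n <- 0L
  for (h in -span:span) for (k in -span:span) for (l in -span:span) {
    if (h == 0 && k == 0 && l == 0) next
    v <- c(h, k, l)
    if (sqrt(sum(v * (G %*% v))) <= 1 / d_min * (1 + 1e-12)) n <- n + 1L
  }
  n
}

test_that("reflection enumeration matches brute force", {
  # cubic a = 10, d_min = 5: h^2+k^2+l^2 <= 4, i.e. 6 + 12 + 8 + 6 = 32
  refl <- enumerate_reflections(toy_cell, d_min = 5)
  expect_equal(nrow(refl), 32L)
  expect_equal(nrow(refl), brute_count_reflections(10, 10, 10, 90, 90, 90, 5, 4))
  expect_true(all(refl$resolution >= 5 - 1e-9))
  expect_false(any(refl$h == 0 & refl$k == 0 & refl$l == 0))

  # d_min beyond the longest axis: nothing diffracts
  expect_equal(nrow(enumerate_reflections(toy_cell, d_min = 11)), 0L)

  # the triclinic reference cell against the metric-tensor oracle
  refl_tri <- enumerate_reflections(tri_cell, d_min = 10)
  expect_equal(nrow(refl_tri),
               brute_count_reflections(64.3, 72, 89.2, 110.6, 107.5, 85.8,
                                       10, 10))

  expect_error(enumerate_reflections(tri_cell, d_min = 0.2), "size limit")
})

test_that("pair entries carry canonical triples", {
  two <- enumerate_reflections(toy_cell, d_min = 5)[c(1, 8), ]
  tab2 <- reference_table(toy_cell, reflections = two, d_min = 5)
  expect_equal(nrow(table_entries(tab2)), 1L)

  ents <- table_entries(toy_table)
  expect_true(all(ents$len_a <= ents$len_b + 1e-15))
  expect_true(all(ents$angle > toy_table$min_angle_sep - 1e-9 &
                  ents$angle < 180 - toy_table$min_angle_sep + 1e-9))

  # (100)/(010): right angle, both lengths 0.1
  ax <- ents[abs(ents$len_a - 0.1) < 1e-12 & abs(ents$len_b - 0.1) < 1e-12 &
             abs(ents$angle - 90) < 1e-9, ]
  expect_gt(nrow(ax), 0)

  # every triple is reproducible from its hkl pair and B
  B <- toy_cell$B
  set.seed(2)
  for (r in sample(nrow(ents), 25)) {
    va <- as.numeric(B %*% c(ents$ha[r], ents$ka[r], ents$la[r]))
    vb <- as.numeric(B %*% c(ents$hb[r], ents$kb[r], ents$lb[r]))
    expect_equal(sort(c(sqrt(sum(va^2)), sqrt(sum(vb^2)))),
                 c(ents$len_a[r], ents$len_b[r]), tolerance = 1e-12)
    co <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    expect_equal(acos(min(1, max(-1, co))) * 180 / pi, ents$angle[r],
                 tolerance = 1e-9)
  }

  # with no angular exclusion: all pairs except the collinear ones, counted
  # by an independent double loop
  tab0 <- reference_table(toy_cell, d_min = 5, min_angle_sep = 0)
  q <- tab0$q
  n_noncol <- 0L
  for (i in 1:(nrow(q) - 1)) for (j in (i + 1):nrow(q)) {
    cr <- c(q[i, 2] * q[j, 3] - q[i, 3] * q[j, 2],
            q[i, 3] * q[j, 1] - q[i, 1] * q[j, 3],
            q[i, 1] * q[j, 2] - q[i, 2] * q[j, 1])
    if (sqrt(sum(cr^2)) > 1e-10) n_noncol <- n_noncol + 1L
  }
  expect_equal(nrow(table_entries(tab0)), n_noncol)
  expect_equal(n_noncol, choose(32, 2) - 28L)   # 18 axis + 6 face + 4 body lines

  expect_error(reference_table(toy_cell,
                               reflections = enumerate_reflections(toy_cell, 5)[1, ]),
               "at least 2")
})

test_that("tolerance queries are equivalent to a linear entry scan", {
  tab <- reference_table(tri_cell, d_min = 15)
  ents <- table_entries(tab)
  linear_scan <- function(la, lb, ang, tl, ta)
    ents[abs(ents$len_a - la) <= tl & abs(ents$len_b - lb) <= tl &
         abs(ents$angle - ang) <= ta, c("ia", "ib")]

  # self-match: an entry's own triple always returns that entry
  set.seed(5)
  for (r in sample(nrow(ents), 20)) {
    hit <- query_table(tab, ents$len_a[r], ents$len_b[r], ents$angle[r],
                       tol_len = 1e-6, tol_angle = 1e-6)
    expect_true(any(hit$ia == ents$ia[r] & hit$ib == ents$ib[r]))
  }

  # zero tolerance on a perturbed triple: empty
  expect_equal(nrow(query_table(tab, ents$len_a[1] + 1e-5, ents$len_b[1],
                                ents$angle[1], tol_len = 0, tol_angle = 0)),
               0L)

  # random queries at assorted tolerances match the exhaustive scan
  for (i in 1:200) {
    la <- runif(1, tab$len_range[1], tab$len_range[2])
    lb <- runif(1, la, tab$len_range[2])
    ang <- runif(1, 5, 175)
    tl <- sample(c(0.0005, 0.0025, 0.01), 1)
    ta <- sample(c(0.2, 1, 5), 1)
    got <- query_table(tab, la, lb, ang, tol_len = tl, tol_angle = ta)
    want <- linear_scan(la, lb, ang, tl, ta)
    expect_equal(got[, c("ia", "ib")],
                 want[order(want$ia, want$ib), ],
                 ignore_attr = TRUE)
  }
})

test_that("table construction is deterministic and cache round-trips", {
  t1 <- reference_table(tri_cell, d_min = 12)
  t2 <- reference_table(tri_cell, d_min = 12)
  expect_identical(t1$hkl, t2$hkl)
  expect_identical(t1$q, t2$q)

  f <- tempfile(fileext = ".tsv")
  write_table_cache(t1, f)
  t3 <- read_table_cache(f)
  expect_equal(t3$hkl, t1$hkl, ignore_attr = TRUE)
  expect_equal(t3$q, t1$q, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(t3$d_min, t1$d_min)
  # serialization is byte-stable
  f2 <- tempfile(fileext = ".tsv")
  write_table_cache(t2, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))

  expect_error(table_entries(toy_table, max_entries = 10), "size limit")
})
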