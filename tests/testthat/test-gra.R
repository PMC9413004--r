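tbl6 <- load_fixture("table6")

test_that("normalization reproduces the published table cell by cell", {
  nrm <- normalize_larger_better(tbl6)
  expect_equal(unname(nrm$x), published_normalized, tolerance = 1e-3,
               ignore_attr = TRUE)
  # extremes of the efficiency column
  expect_equal(unname(nrm$x[15, "EF"]), 0)
  expect_equal(unname(nrm$x[1, "EF"]), 1)
  # every column attains both 0 and 1
  expect_equal(unname(apply(nrm$x, 2, min)), rep(0, 5))
  expect_equal(unname(apply(nrm$x, 2, max)), rep(1, 5))
  # context records the per-response extremes
  expect_equal(nrm$context$min[1], 63.10)
  expect_equal(nrm$context$max[1], 98.60)
  # constant column is refused by name
  bad <- cbind(tbl6[-1], flat = 1)
  expect_error(normalize_larger_better(bad), "flat")
})

test_that("deviations are the complement of the normalized values", {
  nrm <- normalize_larger_better(tbl6)
  d <- deviation_sequences(nrm$x)
  expect_equal(unname(d), 1 - published_normalized, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(nrm$x + d, matrix(1, 18, 5), ignore_attr = TRUE)
  expect_error(deviation_sequences(matrix(c(0.5, 1.2), 1)), "\\[0, 1\\]")
})

test_that("grey relational coefficients follow the psi formula", {
  expect_equal(grey_relational_coefficient(matrix(c(0, 1), 1),
                                           delta_min = 0, delta_max = 1),
               matrix(c(1, 0.5 / 1.5), 1), tolerance = 1e-9)
  expect_equal(grey_relational_coefficient(matrix(c(0.1194, 0, 1), 1))[1, 1],
               0.8072, tolerance = 1e-3)
  # monotone decreasing in the deviation
  d <- matrix(seq(0, 1, by = 0.1), ncol = 1)
  g <- grey_relational_coefficient(d)
  expect_true(all(diff(g[, 1]) < 0))
  expect_error(grey_relational_coefficient(d, psi = 0), "psi")
  expect_error(grey_relational_coefficient(d, psi = 1.5), "psi")
  expect_error(grey_relational_coefficient(matrix(0, 2, 2)), "undefined")
})

test_that("grades are weighted means with competition ranking", {
  run7 <- matrix(c(0.9304, 0.7204, 1.0000, 0.7143, 1.0000), 1)
  expect_equal(grey_relational_grade(run7)$grg, 0.8730, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(grey_relational_grade(matrix(1, 3, 4),
                                     weights = c(0.7, 0.1, 0.1, 0.1))$grg,
               rep(1, 3), ignore_attr = TRUE)
  expect_error(grey_relational_grade(run7, weights = rep(0.3, 5)), "sum to 1")
  expect_error(grey_relational_grade(run7, weights = c(2, -1, 0, 0, 0) / 1),
               "non-negative")
  # ties share a rank and the next is skipped
  tied <- grey_relational_grade(matrix(c(0.9, 0.9, 0.5), ncol = 1),
                                weights = 1)
  expect_equal(tied$rank, c(1L, 1L, 3L))
})

test_that("the full pipeline reproduces the published grade table", {
  g <- gra(tbl6)
  expect_equal(unname(g$grc), published_grc, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(unname(g$grg), published_grg, tolerance = 1e-3)
  expect_equal(unname(g$snr), published_sn_grg, tolerance = 2e-3)
  expect_identical(g$rank, as.integer(published_rank))
  expect_equal(unname(g$grg[7]), 0.8730, tolerance = 1e-3)
  expect_equal(g$rank[7], 1L)
  expect_equal(unname(g$grg[8]), 0.8001, tolerance = 1e-3)
  expect_equal(g$rank[8], 2L)
  expect_equal(unname(g$grg[18]), 0.5384, tolerance = 1e-3)
  expect_equal(g$rank[18], 13L)
  # rank is a permutation of 1..18 (no ties in these data)
  expect_setequal(g$rank, 1:18)
})

test_that("pipeline matches the naive per-cell oracle on random matrices", {
  set.seed(3)
  for (r in 1:10) {
    y <- random_response_matrix()
    psi <- runif(1, 0.1, 1)
    g <- gra(y, psi = psi)
    o <- naive_gra(y, psi = psi)
    expect_equal(unname(g$normalized), o$x, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(g$grc), o$grc, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(g$grg), o$grg, tolerance = 1e-12)
    # grade is a convex combination of the run's coefficients
    expect_true(all(g$grg >= apply(g$grc, 1, min) - 1e-12))
    expect_true(all(g$grg <= apply(g$grc, 1, max) + 1e-12))
    # coefficient bounds for deviations in [0, 1]
    expect_true(all(g$grc >= psi / (1 + psi) - 1e-12 & g$grc <= 1 + 1e-12))
  }
})

test_that("grade ordering is invariant under affine rescaling of a column", {
  set.seed(5)
  y <- random_response_matrix()
  base <- order(gra(y)$grg)
  y2 <- y
  y2[, 3] <- 100 + 7 * y[, 3]
  expect_identical(order(gra(y2)$grg), base)
})

test_that("single-response grades equal that response's coefficients", {
  y <- matrix(runif(12, 1, 9), ncol = 1, dimnames = list(NULL, "Y1"))
  g <- gra(y)
  expect_equal(g$grg, g$grc[, 1], ignore_attr = TRUE)
})

test_that("external scoring reproduces the validation grade", {
  g <- gra(tbl6)
  val <- score_external(load_fixture("table10"), g$context)
  expect_equal(unname(val$grg), 0.8956, tolerance = 1e-3)
  # the validation Aspergillus zone exceeds the design maximum
  expect_true(val$out_of_range[1, "zone_aspergillus"])
  expect_equal(unname(val$normalized[1, "zone_aspergillus"]), 1)
  # without clamping the coefficient exceeds 1 and the run is flagged
  expect_message(
    val_raw <- score_external(load_fixture("table10"), g$context,
                              clamp = FALSE),
    "outside the design range")
  expect_gt(max(val_raw$grc), 1)
  expect_error(score_external(matrix(1, 1, 2), g$context), "response names")
})

test_that("external scoring round-trips every design run", {
  g <- gra(tbl6)
  scored <- score_external(tbl6, g$context)
  expect_equal(unname(scored$grg), unname(g$grg), tolerance = 1e-12)
  # responses at the context maxima give a perfect grade
  best <- matrix(g$context$max, nrow = 1,
                 dimnames = list("1", g$context$response))
  expect_equal(unname(score_external(best, g$context)$grg), 1)
})
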