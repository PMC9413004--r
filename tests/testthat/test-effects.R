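test_that("main effects reproduce the published level means", {
  des <- l18_design()
  eff <- main_effects(des, published_sn_ef)
  # pH (factor B) level 1 mean over runs 1,4,7,10,13,16
  expect_equal(eff$level_means["1", "B"],
               mean(published_sn_ef[c(1, 4, 7, 10, 13, 16)]))
  expect_equal(eff$level_means["1", "B"], 39.5309, tolerance = 1e-3)
  expect_equal(eff$grand_mean, mean(published_sn_ef))
  # balanced design: per-factor mean of level means equals the grand mean
  expect_equal(unname(colMeans(eff$level_means)),
               rep(eff$grand_mean, 5))
  expect_true(all(eff$delta >= 0))
  # pH has the steepest effect on efficiency
  expect_equal(unname(eff$delta_rank["B"]), 1L)
})

test_that("main effects reject unbalanced designs and constant input", {
  a <- l18_design()$assignment
  a[18, "E"] <- 1L
  expect_error(main_effects(a, published_sn_ef), "not balanced")
  eff0 <- main_effects(l18_design(), rep(2.5, 18))
  expect_true(all(eff0$level_means == 2.5))
  expect_true(all(eff0$delta == 0))
})

test_that("optimal-level selection matches the published combinations", {
  des <- l18_design()
  # efficiency alone: A3 B1 C3 D3 E1
  opt_ef <- select_optimal(main_effects(des, snr_table(load_fixture("table4")$EF)))
  expect_equal(unname(opt_ef$levels), c(3L, 1L, 3L, 3L, 1L))
  expect_identical(opt_ef$label, "A_3_B_1_C_3_D_3_E_1_")
  # multi-response grades: A3 B1 C2 D3 E1
  opt_grg <- select_optimal(main_effects(des, published_sn_grg))
  expect_equal(unname(opt_grg$levels), c(3L, 1L, 2L, 3L, 1L))
  expect_identical(opt_grg$label, "A_3_B_1_C_2_D_3_E_1_")
  # pH level 1 carries the highest grade mean
  effg <- main_effects(des, published_sn_grg)
  expect_equal(unname(which.max(effg$level_means[, "B"])), 1L)
})

test_that("ties are surfaced, not broken", {
  opt <- select_optimal(main_effects(l18_design(), rep(1, 18)))
  expect_true(all(opt$ties))
  expect_true(all(is.na(opt$levels)))
  expect_true(all(vapply(opt$candidates, length, integer(1)) == 3L))
  expect_true(is.na(opt$label))
})

test_that("selection is invariant under shifts and response rescaling", {
  des <- l18_design()
  set.seed(42)
  for (rep in 1:5) {
    v <- rnorm(18)
    base <- select_optimal(main_effects(des, v))$candidates
    expect_identical(select_optimal(main_effects(des, v + 7.3))$candidates,
                     base)
    # positive scaling of the underlying response shifts S/N by a constant
    y <- runif(18, 10, 90)
    s1 <- select_optimal(main_effects(des, snr_table(y)))$candidates
    s2 <- select_optimal(main_effects(des, snr_table(3.7 * y)))$candidates
    expect_identical(s1, s2)
  }
})

test_that("additive prediction reproduces published grade arithmetic", {
  des <- l18_design()
  eff <- main_effects(des, published_grg)
  # grand mean of the 18 published grades
  p0 <- predict_additive(eff, c(3, 1, 2, 3, 1), terms = character(0))
  expect_equal(p0$predicted, 0.6269, tolerance = 1e-3)
  # all-term additive prediction at the multi-response optimum
  p5 <- predict_additive(eff, c(3, 1, 2, 3, 1))
  expect_equal(p5$predicted, 0.8712, tolerance = 1e-3)
  expect_error(predict_additive(eff, c(3, 1, 2, 3, 1), terms = "Z"),
               "unknown factor")
})

test_that("additive prediction is exact on noise-free additive data", {
  cfg <- synthetic_config(sigma = rep(0, 5), replicates = 1L)
  sim <- simulate_doe(cfg)
  des <- l18_design()
  eff <- main_effects(des, sim$responses[, 1])
  for (i in c(1, 7, 13, 18)) {
    p <- predict_additive(eff, des$assignment[i, ])
    expect_equal(p$predicted, unname(sim$responses[i, 1]), tolerance = 1e-9)
  }
  # snr-db scale returns the 20log10 back-transform
  effs <- main_effects(des, snr_table(sim$responses[, 1]))
  ps <- predict_additive(effs, des$assignment[7, ], scale = "snr-db")
  expect_equal(ps$back_transformed, 10^(ps$predicted / 20))
})
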