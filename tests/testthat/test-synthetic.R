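test_that("configs are validated and defaults are well-formed", {
  cfg <- synthetic_config()
  expect_s3_class(cfg, "synthetic_config")
  # zero-sum effects per factor and response
  for (f in names(cfg$effects))
    expect_equal(unname(colSums(cfg$effects[[f]])), rep(0, 5),
                 tolerance = 1e-10)
  # planted optimum of the default config
  sim <- simulate_doe(cfg, seed = 1)
  expect_equal(unname(sim$truth$optimum), c(3L, 1L, 2L, 3L, 1L))
  # violating zero-sum is refused
  eff <- cfg$effects
  eff$A[1, 1] <- eff$A[1, 1] + 1
  expect_error(synthetic_config(effects = eff), "sum to zero")
  expect_error(synthetic_config(sigma = c(-1, 1, 1, 1, 1)), "non-negative")
})

test_that("generation is deterministic and respects response bounds", {
  cfg <- synthetic_config(sigma = c(8, 4, 4, 4, 4))
  s1 <- simulate_doe(cfg, seed = 99)
  s2 <- simulate_doe(cfg, seed = 99)
  expect_identical(s1$responses, s2$responses)
  s3 <- simulate_doe(cfg, seed = 100)
  expect_false(identical(s1$responses, s3$responses))
  # bounds: efficiency in (0, 100], zones positive, even under heavy noise
  set.seed(2)
  for (r in 1:10) {
    y <- simulate_doe(synthetic_config(sigma = c(50, 30, 30, 30, 30)))$responses
    expect_true(all(y[, 1] > 0 & y[, 1] <= 100))
    expect_true(all(y[, -1] > 0))
  }
})

test_that("zero noise reproduces the additive surface exactly", {
  cfg <- synthetic_config(sigma = rep(0, 5), replicates = 1L)
  sim <- simulate_doe(cfg, seed = 4)
  expect_equal(sim$responses[, 1], sim$truth$surface[, 1], tolerance = 1e-12)
  # zone columns only differ by the 2-dp recording convention
  expect_true(max(abs(sim$responses[, -1] - sim$truth$surface[, -1])) <= 0.005)
  expect_false(any(attr(sim$responses, "clipped")))
})

test_that("the noise-free pipeline recovers the planted optimum", {
  cfg <- synthetic_config(sigma = rep(0, 5))
  sim <- simulate_doe(cfg, seed = 8)
  g <- gra(sim$responses)
  opt <- select_optimal(main_effects(cfg$design, snr_table(g$grg)))
  expect_equal(unname(opt$levels), unname(sim$truth$optimum))
  expect_equal(recovery_experiment(cfg, 3, seed = 1)$joint, 1.0)
  # ANOVA error SS vanishes on the unrounded efficiency response
  an <- doe_anova(cfg$design, sim$responses[, 1])
  expect_lt(an$SumSq[6] / an$SumSq[7], 1e-12)
})

test_that("single-factor signal concentrates its sum of squares", {
  cfg <- synthetic_config()
  eff <- lapply(cfg$effects, function(m) m * 0)
  eff$B[, 1] <- c(6, 0, -6)
  cfg1 <- synthetic_config(effects = eff, sigma = c(0.05, 0, 0, 0, 0),
                           replicates = 1L)
  sim <- simulate_doe(cfg1, seed = 12)
  an <- doe_anova(cfg1$design, sim$responses[, 1])
  ss <- an$SumSq[1:5]
  expect_gt(ss[2] / sum(ss), 0.99)
})

test_that("null effects give chance-level per-factor recovery", {
  cfg0 <- synthetic_config(effect_scale = 0)
  res <- recovery_experiment(cfg0, 1000, seed = 20)
  # each level equally likely: rate 1/3, binomial SE ~ 0.0149
  se <- sqrt((1 / 3) * (2 / 3) / 1000)
  expect_true(all(abs(res$per_factor - 1 / 3) < 3 * se))
})

test_that("recovery improves monotonically with effect size", {
  rates <- vapply(c(0.15, 0.6, 2.5), function(scale) {
    cfg <- synthetic_config(effect_scale = scale)
    recovery_experiment(cfg, 60, seed = 31)$joint
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1.0)
})
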