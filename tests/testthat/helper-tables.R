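# Published reference tables of the flocculation case study, frozen as test
# expectations, plus independent brute-force oracles.

# Published per-run S/N column for the flocculation efficiency (dB).
published_sn_ef <- c(
  39.8776, 39.7918, 37.6883, 39.0104, 37.6230, 37.3566, 39.7598, 39.7886,
  38.0431, 39.6045, 38.7263, 37.5323, 39.4797, 38.4176, 36.0008, 39.4531,
  39.2346, 37.2631)

# Published normalized values (18 runs x 5 responses).
published_normalized <- matrix(c(
  1.0000, 0.8806, 0.9429, 0.7500, 0.5636,
  0.9727, 0.9104, 0.4571, 0.8500, 0.3455,
  0.3812, 0.0000, 0.0000, 0.6000, 0.8182,
  0.7361, 0.9403, 0.4857, 0.5500, 0.8545,
  0.3650, 0.9254, 0.4857, 0.5500, 0.7273,
  0.3003, 0.8507, 0.3143, 0.4500, 0.5091,
  0.9626, 0.8060, 1.0000, 0.8000, 1.0000,
  0.9717, 0.7910, 0.7714, 0.9500, 0.8364,
  0.4712, 0.9552, 0.8571, 0.5000, 0.8000,
  0.9141, 0.2985, 0.2286, 1.0000, 0.0000,
  0.6552, 0.3881, 0.2857, 0.8000, 0.3818,
  0.3428, 0.4478, 0.2857, 0.5500, 0.2000,
  0.8756, 0.7910, 1.0000, 0.8500, 0.6182,
  0.5703, 0.6716, 0.4571, 0.6500, 0.5091,
  0.0000, 0.4030, 0.2286, 0.0000, 0.8000,
  0.8675, 0.7910, 0.4857, 0.6000, 0.7818,
  0.8018, 1.0000, 0.5143, 0.5000, 0.7636,
  0.2781, 0.5224, 0.2000, 0.4000, 0.9636), ncol = 5, byrow = TRUE)

# Published grey relational coefficients (18 x 5).
published_grc <- matrix(c(
  1.0000, 0.8072, 0.8974, 0.6667, 0.5340,
  0.9482, 0.8481, 0.4795, 0.7692, 0.4331,
  0.4469, 0.3333, 0.3333, 0.5556, 0.7333,
  0.6545, 0.8933, 0.4930, 0.5263, 0.7746,
  0.4405, 0.8701, 0.4930, 0.5263, 0.6471,
  0.4168, 0.7701, 0.4217, 0.4762, 0.5046,
  0.9304, 0.7204, 1.0000, 0.7143, 1.0000,
  0.9464, 0.7053, 0.6863, 0.9091, 0.7534,
  0.4860, 0.9178, 0.7778, 0.5000, 0.7143,
  0.8533, 0.4161, 0.3933, 1.0000, 0.3333,
  0.5919, 0.4497, 0.4118, 0.7143, 0.4472,
  0.4321, 0.4752, 0.4118, 0.5263, 0.3846,
  0.8008, 0.7053, 1.0000, 0.7692, 0.5670,
  0.5378, 0.6036, 0.4795, 0.5882, 0.5046,
  0.3333, 0.4558, 0.3933, 0.3333, 0.7143,
  0.7906, 0.7053, 0.4930, 0.5556, 0.6962,
  0.7161, 1.0000, 0.5072, 0.5000, 0.6790,
  0.4092, 0.5115, 0.3846, 0.4545, 0.9322), ncol = 5, byrow = TRUE)

published_grg <- c(
  0.7811, 0.6956, 0.4805, 0.6684, 0.5954, 0.5179, 0.8730, 0.8001, 0.6792,
  0.5992, 0.5229, 0.4460, 0.7685, 0.5427, 0.4460, 0.6481, 0.6805, 0.5384)

published_sn_grg <- c(
  -2.14629, -3.15261, -6.36628, -3.49982, -4.50383, -5.71558, -1.17951,
  -1.93719, -3.36039, -4.44838, -5.63086, -7.01354, -2.28754, -5.30826,
  -7.01333, -3.76703, -3.34368, -5.37790)

published_rank <- c(3, 5, 16, 8, 11, 15, 1, 2, 7, 10, 14, 18, 4, 12, 17, 9,
                    6, 13)

# Published ANOVA sums of squares / F values.
published_anova_ef <- list(
  ss = c(A = 3.3618, B = 15.7743, C = 0.1697, D = 0.0064, E = 1.4295),
  f = c(A = 7.72, B = 36.24, C = 0.39, D = 0.01, E = 3.28),
  error_ss = 1.5234, total_ss = 22.2650)
published_anova_grg <- list(
  ss = c(A = 10.2073, B = 26.1180, C = 1.3837, D = 0.3583, E = 3.0274),
  f = c(A = 3.01, B = 7.71, C = 0.41, D = 0.11, E = 0.89),
  error_ss = 11.8635, total_ss = 52.9581)

# --- independent oracles -------------------------------------------------

# Naive per-cell grey relational pipeline: explicit loops, no vectorization,
# sharing no code with the package internals.
naive_gra <- function(y, psi = 0.5, weights = rep(1 / ncol(y), ncol(y))) {
  n <- nrow(y); p <- ncol(y)
  x <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    lo <- min(y[, j]); hi <- max(y[, j])
    for (i in seq_len(n)) x[i, j] <- (y[i, j] - lo) / (hi - lo)
  }
  d <- 1 - x
  dmin <- min(d); dmax <- max(d)
  grc <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) for (j in seq_len(p))
    grc[i, j] <- (dmin + psi * dmax) / (d[i, j] + psi * dmax)
  grg <- numeric(n)
  for (i in seq_len(n)) grg[i] <- sum(weights * grc[i, ])
  list(x = x, d = d, grc = grc, grg = grg)
}

# Two-pass brute-force balanced ANOVA: explicit group means and residuals.
naive_anova_ss <- function(assignment, values) {
  gm <- mean(values)
  ss <- sapply(seq_len(ncol(assignment)), function(j) {
    s <- 0
    for (l in 1:3) {
      idx <- assignment[, j] == l
      s <- s + sum(idx) * (mean(values[idx]) - gm)^2
    }
    s
  })
  names(ss) <- colnames(assignment)
  c(ss, error = sum((values - gm)^2) - sum(ss),
    total = sum((values - gm)^2))
}

# Per-element absolute agreement, the form the published rounding supports.
expect_max_abs <- function(actual, expected, tol) {
  expect_lt(max(abs(unname(actual) - unname(expected))), tol)
}

random_response_matrix <- function(n = 18, p = 5) {
  m <- matrix(runif(n * p, 10, 100), n, p)
  colnames(m) <- paste0("Y", seq_len(p))
  m
}
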