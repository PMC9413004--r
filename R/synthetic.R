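# Synthetic designed-experiment generator: additive main-effects truth with
# planted optimum, Gaussian noise, triplicate zone means, and recovery
# experiments.

# Effect pattern with the maximum at `peak`, zero-sum across the 3 levels.
.peak_pattern <- function(peak, amplitude) {
  e <- rep(-amplitude / 2, 3)
  e[peak] <- amplitude
  e
}

#' Configuration for the synthetic experiment generator
#'
#' Defines an additive main-effects truth model over a balanced design:
#' per-response baselines, zero-sum per-factor level effects, and Gaussian
#' measurement noise. The default configuration plants the optimum at
#' combination A3 B1 C2 D3 E1 and produces responses on the scale of the
#' flocculation study: efficiency around 80-96 % and inhibition zones around
#' 30-41 mm, with factor amplitudes ordered like the observed factor
#' importance (pH strongest, rapid mixing weakest).
#'
#' @param design A `taguchi_design`; default [l18_design()].
#' @param baseline Named per-response baseline values \eqn{\mu_j}. The first
#'   response is treated as a percentage efficiency confined to (0, 100]; the
#'   remaining ones as positive zone diameters.
#' @param effects A list (one element per factor, names = factor notations)
#'   of 3 x p matrices of level effects \eqn{e_{f,l,j}}; each column must sum
#'   to zero (identifiability). `NULL` builds the default planted-optimum
#'   effects.
#' @param sigma Per-response noise standard deviations (EF: per measurement;
#'   zones: per replicate).
#' @param replicates Number of replicate draws averaged for zone responses
#'   (default 3, mimicking triplicate plate reads).
#' @param optimum Planted optimal levels used to build default effects
#'   (ignored when `effects` is supplied).
#' @param effect_scale Multiplier applied to the default effect amplitudes
#'   (0 gives a null model with no factor effects).
#' @return A `synthetic_config` list, validated.
#' @examples
#' cfg <- synthetic_config(effect_scale = 0.5)
#' @export
synthetic_config <- function(design = l18_design(),
                             baseline = c(EF = 82, zone_xanthomonas = 34,
                                          zone_colletotrichum = 34,
                                          zone_fusarium = 34,
                                          zone_aspergillus = 34),
                             effects = NULL,
                             sigma = c(2, 1, 1, 1, 1),
                             replicates = 3L,
                             optimum = c(3L, 1L, 2L, 3L, 1L),
                             effect_scale = 1) {
  a <- design_assignment(design)
  fac <- colnames(a)
  p <- length(baseline)
  if (length(sigma) != p)
    stop("sigma must have one entry per response", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (is.null(effects)) {
    # Amplitudes per factor (columns = responses): EF mirrors the observed
    # importance ordering B > A > E > C > D; zones share the same ordering
    # at a smaller scale.
    amp_ef <- c(A = 4, B = 6, C = 1, D = 0.5, E = 2.5) * effect_scale
    amp_zone <- c(A = 3, B = 2.5, C = 1, D = 0.5, E = 2) * effect_scale
    effects <- lapply(seq_along(fac), function(j) {
      m <- cbind(.peak_pattern(optimum[j], amp_ef[j]),
                 matrix(rep(.peak_pattern(optimum[j], amp_zone[j]), p - 1),
                        nrow = 3))
      colnames(m) <- names(baseline)
      m
    })
    names(effects) <- fac
  }
  for (f in fac) {
    m <- effects[[f]]
    if (is.null(m) || !all(dim(m) == c(3L, p)))
      stop("effects[['", f, "']] must be a 3 x ", p, " matrix", call. = FALSE)
    if (any(abs(colSums(m)) > 1e-8))
      stop("effects for factor ", f, " must sum to zero within each response",
           call. = FALSE)
  }
  structure(list(design = design, baseline = baseline, effects = effects,
                 sigma = sigma, replicates = as.integer(replicates)),
            class = "synthetic_config")
}

# Noise-free additive surface (runs x responses).
noise_free_surface <- function(config) {
  a <- design_assignment(config$design)
  p <- length(config$baseline)
  surf <- matrix(rep(config$baseline, each = nrow(a)), nrow = nrow(a),
                 dimnames = list(rownames(a), names(config$baseline)))
  for (j in seq_len(ncol(a))) {
    f <- colnames(a)[j]
    surf <- surf + config$effects[[f]][a[, j], , drop = FALSE]
  }
  surf
}

#' Generate a synthetic designed-experiment response matrix
#'
#' Draws responses \eqn{y_{ij} = \mu_j + \sum_f e_{f, l_f(i), j} +
#' \varepsilon_{ij}} with Gaussian noise. The first response is treated as an
#' efficiency percentage and clipped to (0.01, 100]; the remaining responses
#' are means of `replicates` independent draws, rounded to 2 decimals
#' (mimicking triplicate zone reads) and floored at 0.01. Clipping is
#' reported via the `clipped` attribute of the response matrix.
#'
#' @param config A `synthetic_config`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `responses` (runs x responses matrix, attribute
#'   `clipped` marking cells altered by the bounds) and `truth` (list with
#'   `optimum`, the planted per-factor argmax of the equal-weight summed
#'   effects, and `surface`, the noise-free response matrix).
#' @examples
#' sim <- simulate_doe(synthetic_config(sigma = rep(0, 5)))
#' all(sim$responses[, 1] == sim$truth$surface[, 1])
#' @export
simulate_doe <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  surf <- noise_free_surface(config)
  n <- nrow(surf); p <- ncol(surf)
  y <- surf
  # efficiency: single measurement
  y[, 1] <- surf[, 1] + stats::rnorm(n, 0, config$sigma[1])
  # zones: mean of replicate draws, rounded to 2 dp as recorded on the bench
  if (p > 1) for (j in 2:p) {
    reps <- matrix(stats::rnorm(n * config$replicates, 0, config$sigma[j]),
                   nrow = n)
    y[, j] <- round(surf[, j] + rowMeans(reps), 2)
  }
  clipped <- matrix(FALSE, n, p, dimnames = dimnames(y))
  lo <- 0.01
  clipped[, 1] <- y[, 1] < lo | y[, 1] > 100
  y[, 1] <- pmin(pmax(y[, 1], lo), 100)
  if (p > 1) {
    clipped[, -1] <- y[, -1, drop = FALSE] < lo
    y[, -1] <- pmax(y[, -1, drop = FALSE], lo)
  }
  attr(y, "clipped") <- clipped
  fac <- colnames(design_assignment(config$design))
  optimum <- vapply(fac, function(f)
    which.max(rowSums(config$effects[[f]])), integer(1))
  list(responses = y, truth = list(optimum = optimum, surface = surf))
}

#' Planted-optimum recovery experiment
#'
#' Repeatedly generates synthetic data, runs the full multi-response pipeline
#' (GRA grades, S/N conversion, main effects, optimal-level selection) and
#' measures how often the planted optimum is recovered: per factor, and
#' jointly over all factors. A tie in the selected level counts as a miss.
#'
#' @param config A `synthetic_config`.
#' @param repetitions Number of simulated experiments (>= 1).
#' @param seed Optional integer seed.
#' @param psi,weights Passed to [gra()].
#' @return A list with `per_factor` (named recovery rates), `joint` (rate of
#'   full-combination recovery) and `repetitions`.
#' @examples
#' recovery_experiment(synthetic_config(sigma = rep(0, 5)), 3, seed = 1)$joint
#' @export
recovery_experiment <- function(config, repetitions, seed = NULL,
                                psi = 0.5, weights = NULL) {
  stopifnot(inherits(config, "synthetic_config"), repetitions >= 1)
  if (!is.null(seed)) set.seed(seed)
  des <- config$design
  fac <- colnames(design_assignment(des))
  hits <- matrix(FALSE, repetitions, length(fac),
                 dimnames = list(NULL, fac))
  joint <- logical(repetitions)
  for (r in seq_len(repetitions)) {
    sim <- simulate_doe(config)
    g <- gra(sim$responses, psi = psi, weights = weights)
    opt <- select_optimal(main_effects(des, snr_table(g$grg)))
    sel <- opt$levels # NA where tied -> never a hit
    hits[r, ] <- !is.na(sel) & sel == sim$truth$optimum
    joint[r] <- all(hits[r, ])
  }
  list(per_factor = colMeans(hits), joint = mean(joint),
       repetitions = repetitions)
}
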