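# Grey relational analysis: normalization, deviation sequences, grey
# relational coefficients and grades, ranking, and validation scoring.

# Coerce a runs x responses input (matrix, or data.frame with an optional
# `run` column) to a numeric matrix with run ids as rownames.
as_response_matrix <- function(x) {
  if (is.data.frame(x)) {
    run <- if ("run" %in% names(x)) x$run else seq_len(nrow(x))
    x <- as.matrix(x[setdiff(names(x), "run")])
    rownames(x) <- as.character(run)
  } else {
    x <- as.matrix(x)
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  }
  if (!is.numeric(x)) stop("responses must be numeric", call. = FALSE)
  if (anyNA(x)) stop("responses must not contain missing cells", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("Y", seq_len(ncol(x)))
  x
}

#' Larger-the-better normalization
#'
#' Rescales each response column to \eqn{[0, 1]} by
#' \eqn{X_{ij} = (Y_{ij} - \min_j Y) / (\max_j Y - \min_j Y)},
#' so that the best (largest) observed value of every response maps to 1 and
#' the worst to 0. The per-response min/max form the normalization context,
#' needed later to score runs performed outside the design
#' (see [score_external()]).
#'
#' @param responses Runs x responses matrix or data.frame (a `run` column, if
#'   present, becomes row names). All responses are treated as
#'   larger-the-better.
#' @return A list with `x` (the normalized matrix) and `context` (data.frame
#'   with columns `response`, `min`, `max`).
#' @examples
#' normalize_larger_better(load_fixture("table6"))$x[15, "EF"] # 0: column min
#' @export
normalize_larger_better <- function(responses) {
  y <- as_response_matrix(responses)
  mins <- apply(y, 2, min)
  maxs <- apply(y, 2, max)
  degenerate <- maxs <= mins
  if (any(degenerate))
    stop("response(s) with zero range cannot be normalized: ",
         paste(colnames(y)[degenerate], collapse = ", "), call. = FALSE)
  x <- sweep(sweep(y, 2, mins, "-"), 2, maxs - mins, "/")
  list(x = x,
       context = data.frame(response = colnames(y), min = unname(mins),
                            max = unname(maxs), stringsAsFactors = FALSE))
}

#' Deviation sequences
#'
#' The per-cell quality loss from the ideal: \eqn{\Delta_{ij} = 1 - X_{ij}}.
#'
#' @param normalized Matrix of normalized values in \eqn{[0, 1]}.
#' @return Matrix of deviations, same shape.
#' @export
deviation_sequences <- function(normalized) {
  normalized <- as.matrix(normalized)
  if (any(normalized < -1e-12 | normalized > 1 + 1e-12))
    stop("normalized values must lie in [0, 1]", call. = FALSE)
  1 - normalized
}

#' Grey relational coefficients
#'
#' Converts deviations into coefficients in \eqn{(\psi/(1+\psi), 1]}:
#' \deqn{GRC_{ij} = (\Delta_{min} + \psi \Delta_{max}) /
#'       (\Delta_{ij} + \psi \Delta_{max})}
#' with \eqn{\Delta_{min}}, \eqn{\Delta_{max}} the global extremes of the
#' deviation matrix. After larger-the-better normalization over the design
#' runs these are 0 and 1, so per-column and global conventions coincide; for
#' out-of-design scoring they are fixed at 0 and 1 explicitly. The
#' distinguishing coefficient \eqn{\psi} tunes how sharply the coefficient
#' discriminates between deviations; 0.5 by convention.
#'
#' @param deviations Matrix of non-negative deviations.
#' @param psi Distinguishing coefficient in (0, 1].
#' @param delta_min,delta_max Global deviation extremes; default the observed
#'   ones.
#' @return Matrix of grey relational coefficients.
#' @examples
#' grey_relational_coefficient(matrix(c(0, 1, 0.1194, 0.5), 2)) # 1, 1/3, ...
#' @export
grey_relational_coefficient <- function(deviations, psi = 0.5,
                                        delta_min = NULL, delta_max = NULL) {
  d <- as.matrix(deviations)
  if (any(d < -1e-12)) stop("deviations must be non-negative", call. = FALSE)
  if (!is.numeric(psi) || length(psi) != 1L || psi <= 0 || psi > 1)
    stop("psi must lie in (0, 1]", call. = FALSE)
  if (is.null(delta_min)) delta_min <- min(d)
  if (is.null(delta_max)) delta_max <- max(d)
  if (delta_max <= 0)
    stop("all deviations are zero; grey relational coefficients are undefined",
         call. = FALSE)
  (delta_min + psi * delta_max) / (d + psi * delta_max)
}

#' Grey relational grade and ranking
#'
#' Aggregates each run's grey relational coefficients into a single grade,
#' the weighted mean \eqn{GRG_i = \sum_j w_j GRC_{ij}} (equal weights by
#' default), and ranks the runs by descending grade (rank 1 = best). Equal
#' grades share a rank and the next rank is skipped (competition ranking).
#'
#' @param grc Matrix of grey relational coefficients (runs x responses).
#' @param weights Non-negative response weights summing to 1; `NULL` for
#'   equal weights.
#' @return A list with `grg` (named numeric vector) and `rank` (integer
#'   vector, 1 = best).
#' @export
grey_relational_grade <- function(grc, weights = NULL) {
  grc <- as.matrix(grc)
  if (is.null(weights)) weights <- rep(1 / ncol(grc), ncol(grc))
  if (length(weights) != ncol(grc))
    stop("need one weight per response", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  grg <- drop(grc %*% weights)
  names(grg) <- rownames(grc)
  list(grg = grg, rank = as.integer(rank(-grg, ties.method = "min")))
}

#' Grey relational analysis pipeline
#'
#' Runs the full chain: larger-the-better normalization, deviation sequences,
#' grey relational coefficients, weighted grades, decibel S/N conversion of
#' the grades, and ranking. The normalization context (per-response min/max
#' over the design runs) is retained for scoring later validation runs.
#'
#' @param responses Runs x responses matrix or data.frame, all
#'   larger-the-better.
#' @param psi Distinguishing coefficient in (0, 1]; default 0.5.
#' @param weights Response weights (non-negative, sum 1); `NULL` for equal.
#' @return A `gra_result` object with elements `responses`, `normalized`,
#'   `deviations`, `grc`, `grg`, `snr`, `rank`, `psi`, `weights`, `context`.
#' @examples
#' g <- gra(load_fixture("table6"))
#' round(g$grg[g$rank == 1], 4) # run 7, grade 0.8730
#' @export
gra <- function(responses, psi = 0.5, weights = NULL) {
  y <- as_response_matrix(responses)
  if (is.null(weights)) weights <- rep(1 / ncol(y), ncol(y))
  nrm <- normalize_larger_better(y)
  dev <- deviation_sequences(nrm$x)
  grc <- grey_relational_coefficient(dev, psi = psi)
  gg <- grey_relational_grade(grc, weights)
  structure(list(responses = y, normalized = nrm$x, deviations = dev,
                 grc = grc, grg = gg$grg, snr = snr_table(gg$grg),
                 rank = gg$rank, psi = psi, weights = weights,
                 context = nrm$context),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("Grey relational analysis: %d runs, %d responses (psi = %g)\n",
              nrow(x$grc), ncol(x$grc), x$psi))
  df <- data.frame(run = rownames(x$grc),
                   round(x$grc, 4),
                   GRG = sprintf("%.4f", x$grg),
                   `S/N` = sprintf("%.5f", x$snr),
                   Rank = x$rank, check.names = FALSE)
  print(df, row.names = FALSE)
  best <- which(x$rank == 1L)[1]
  cat(sprintf("Best run: %s (GRG %.4f)\n", rownames(x$grc)[best], x$grg[best]))
  invisible(x)
}

#' Score out-of-design runs against a stored normalization context
#'
#' Normalizes new response vectors with the per-response min/max recorded
#' from the design runs (the context is *not* refreshed), then applies the
#' grey relational coefficient and grade exactly as for in-design runs, with
#' the global deviation extremes fixed at 0 and 1. A validation run can beat
#' the design maximum of a response; with `clamp = TRUE` (default) its
#' normalized value is clipped to 1 (deviation 0) so the coefficient stays in
#' \eqn{[\psi/(1+\psi), 1]}. With `clamp = FALSE` the raw normalized values
#' are used and out-of-range cells are flagged; coefficients may then exceed
#' 1.
#'
#' @param new_responses One or more runs x responses (matrix, data.frame or a
#'   single named vector) with the same response names as the context.
#' @param context Normalization context data.frame from [gra()] or
#'   [normalize_larger_better()].
#' @param psi Distinguishing coefficient; default 0.5.
#' @param weights Response weights; `NULL` for equal.
#' @param clamp Clip normalized values to \eqn{[0, 1]} before computing
#'   deviations (default `TRUE`).
#' @return An `external_score` object: `grg`, `grc`, `normalized`,
#'   `out_of_range` (logical matrix of cells outside the design range),
#'   `clamp`.
#' @examples
#' g <- gra(load_fixture("table6"))
#' score_external(load_fixture("table10"), g$context)$grg # 0.8957
#' @export
score_external <- function(new_responses, context, psi = 0.5, weights = NULL,
                           clamp = TRUE) {
  if (is.numeric(new_responses) && is.null(dim(new_responses)) &&
      !is.data.frame(new_responses))
    new_responses <- matrix(new_responses, nrow = 1,
                            dimnames = list("1", names(new_responses)))
  y <- as_response_matrix(new_responses)
  if (!setequal(colnames(y), context$response) ||
      anyDuplicated(colnames(y)))
    stop("response names must match the normalization context (",
         paste(context$response, collapse = ", "), ")", call. = FALSE)
  y <- y[, context$response, drop = FALSE]
  rng <- context$max - context$min
  x <- sweep(sweep(y, 2, context$min, "-"), 2, rng, "/")
  out_of_range <- x < 0 | x > 1
  if (clamp) x <- pmin(pmax(x, 0), 1)
  d <- 1 - x
  grc <- (0 + psi * 1) / (d + psi * 1)
  if (is.null(weights)) weights <- rep(1 / ncol(y), ncol(y))
  gg <- grey_relational_grade(grc, weights)
  if (!clamp && any(out_of_range))
    message("score_external: ", sum(out_of_range),
            " response value(s) outside the design range; ",
            "coefficients may exceed 1")
  structure(list(grg = gg$grg, grc = grc, normalized = x,
                 out_of_range = out_of_range, psi = psi, weights = weights,
                 clamp = clamp),
            class = "external_score")
}

#' @export
print.external_score <- function(x, ...) {
  cat("External scoring (clamp =", x$clamp, ", psi =", x$psi, ")\n")
  df <- data.frame(run = names(x$grg), GRG = sprintf("%.4f", x$grg),
                   out_of_range = rowSums(x$out_of_range))
  print(df, row.names = FALSE)
  invisible(x)
}
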