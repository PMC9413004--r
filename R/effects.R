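# Main-effects analysis, optimal-level selection, additive prediction.

#' Main-effects table for a balanced design
#'
#' For each factor, the mean of the analysed value over the runs at each of
#' its three levels, together with the factor delta (largest minus smallest
#' level mean) and the delta rank across factors. In a balanced design each
#' level mean averages the same number of runs, so the mean of a factor's
#' three level means equals the grand mean.
#'
#' @param design A `taguchi_design` (or level-index matrix); must be
#'   level-balanced, otherwise level means would be confounded and an error
#'   is raised.
#' @param values Per-run numeric vector (e.g. S/N ratios), one value per run.
#' @return A `main_effects` object: `level_means` (3 x k matrix, rows =
#'   levels, columns = factors), `delta`, `delta_rank`, `grand_mean`, and the
#'   factor `notation`.
#' @examples
#' des <- l18_design()
#' sn <- snr_table(load_fixture("table4")$EF)
#' main_effects(des, sn)$level_means["1", "B"] # 39.53 dB at pH 5
#' @export
main_effects <- function(design, values) {
  a <- design_assignment(design)
  if (length(values) != nrow(a))
    stop("values must have one entry per design run", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  bal <- check_balance(a)
  if (!bal$balanced)
    stop("design is not balanced: ", paste(bal$violations, collapse = "; "),
         call. = FALSE)
  lev <- sort(unique(as.vector(a)))
  level_means <- vapply(seq_len(ncol(a)), function(j)
    vapply(lev, function(l) mean(values[a[, j] == l]), numeric(1)),
    numeric(length(lev)))
  dimnames(level_means) <- list(level = lev, factor = colnames(a))
  delta <- apply(level_means, 2, function(m) max(m) - min(m))
  structure(list(level_means = level_means,
                 delta = delta,
                 delta_rank = rank(-delta, ties.method = "min"),
                 grand_mean = mean(values),
                 notation = colnames(a)),
            class = "main_effects")
}

#' @export
print.main_effects <- function(x, digits = 4, ...) {
  cat("Main effects (grand mean ", format(x$grand_mean, digits = 6), ")\n",
      sep = "")
  tab <- rbind(round(x$level_means, digits),
               Delta = round(x$delta, digits),
               Rank = x$delta_rank)
  print(tab)
  invisible(x)
}

#' Optimal level per factor
#'
#' Selects, for each factor, the level with the largest level mean
#' (larger-the-better). Exact ties are surfaced, not silently broken: tied
#' factors get `NA` in `levels` and all argmax levels in `candidates`.
#'
#' @param effects A `main_effects` object.
#' @return An `optimal_combination` object: `levels` (named integer vector,
#'   `NA` where tied), `candidates` (list of argmax level sets per factor),
#'   `ties` (logical vector), and `label` (the combination label, `NA` if any
#'   factor is tied).
#' @examples
#' sn <- snr_table(load_fixture("table4")$EF)
#' select_optimal(main_effects(l18_design(), sn))$levels # A3 B1 C3 D3 E1
#' @export
select_optimal <- function(effects) {
  stopifnot(inherits(effects, "main_effects"))
  lm <- effects$level_means
  candidates <- lapply(seq_len(ncol(lm)), function(j) {
    m <- lm[, j]
    as.integer(rownames(lm)[m == max(m)])
  })
  names(candidates) <- colnames(lm)
  ties <- lengths(candidates) > 1L
  levels <- vapply(candidates, function(cc)
    if (length(cc) == 1L) cc else NA_integer_, integer(1))
  label <- if (anyNA(levels)) NA_character_ else format_combination(levels)
  structure(list(levels = levels, candidates = candidates, ties = ties,
                 label = label),
            class = "optimal_combination")
}

#' @export
print.optimal_combination <- function(x, ...) {
  if (any(x$ties)) {
    cat("Optimal levels (ties present):\n")
    for (f in names(x$candidates))
      cat(" ", f, ": ", paste(x$candidates[[f]], collapse = "/"),
          if (x$ties[[f]]) " (tie)", "\n", sep = "")
  } else {
    cat("Optimal combination:", x$label, "\n")
  }
  invisible(x)
}

#' Additive main-effects prediction
#'
#' Predicts the response at an arbitrary level combination under the additive
#' (no-interaction) model: the grand mean plus, for each included factor, the
#' deviation of its chosen level mean from the grand mean. With an empty term
#' set the prediction is the grand mean. When the effects were computed on
#' the decibel S/N scale, `scale = "snr-db"` additionally reports the
#' back-transform `10^(pred/20)` on the original response scale.
#'
#' The study's own predicted validation grade is not exactly recoverable by
#' any documented variant of this formula (the published prediction method is
#' unstated); the all-term value-scale prediction is the default and the
#' divergence is documented in the methods vignette.
#'
#' @param effects A `main_effects` object.
#' @param combination Integer vector, one level index per factor.
#' @param terms Factors to include as additive terms (character vector of
#'   factor notations); `NULL` means all factors.
#' @param scale `"value"` if the effects are on the raw response scale,
#'   `"snr-db"` if on the decibel S/N scale.
#' @return An `additive_prediction` object: `combination`, `terms`, `scale`,
#'   `predicted`, and (for `"snr-db"`) `back_transformed`.
#' @examples
#' g <- gra(load_fixture("table6"))
#' eff <- main_effects(l18_design(), g$grg)
#' predict_additive(eff, c(3, 1, 2, 3, 1))$predicted
#' @export
predict_additive <- function(effects, combination, terms = NULL,
                             scale = c("value", "snr-db")) {
  stopifnot(inherits(effects, "main_effects"))
  scale <- match.arg(scale)
  fac <- effects$notation
  combination <- as.integer(combination)
  if (length(combination) != length(fac) || anyNA(combination))
    stop("combination must give one level per factor", call. = FALSE)
  if (is.null(terms)) terms <- fac
  unknown <- setdiff(terms, fac)
  if (length(unknown))
    stop("unknown factor(s) in terms: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pred <- effects$grand_mean
  for (f in terms) {
    j <- match(f, fac)
    pred <- pred + effects$level_means[combination[j], j] - effects$grand_mean
  }
  out <- list(combination = stats::setNames(combination, fac),
              terms = terms, scale = scale, predicted = pred)
  if (scale == "snr-db") out$back_transformed <- 10^(pred / 20)
  structure(out, class = "additive_prediction")
}

#' @export
print.additive_prediction <- function(x, ...) {
  cat("Additive prediction at", format_combination(x$combination),
      "\n  terms:", if (length(x$terms)) paste(x$terms, collapse = ", ") else "(none)",
      "\n  scale:", x$scale,
      "\n  predicted:", format(x$predicted, digits = 6), "\n")
  if (!is.null(x$back_transformed))
    cat("  back-transformed response:", format(x$back_transformed, digits = 6), "\n")
  invisible(x)
}
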