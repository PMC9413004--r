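# Balanced fixed-effects ANOVA of per-run values (typically S/N ratios).

#' Balanced no-interaction ANOVA
#'
#' Fixed-effects analysis of variance of a per-run value over the factors of
#' a balanced three-level design, with no interaction terms. For a balanced
#' design the sums of squares decompose exactly:
#' factor SS \eqn{= r \sum_l (\bar y_l - \bar y)^2} (with \eqn{r} runs per
#' level, 6 in the L18), total SS \eqn{= \sum_i (y_i - \bar y)^2}, and the
#' error SS is the remainder. Each factor carries 2 degrees of freedom; with
#' the L18 and five factors the error has \eqn{17 - 10 = 7}. F-ratios are
#' factor MS over error MS and p-values come from the upper tail of the
#' F(2, error df) distribution.
#'
#' @param design A `taguchi_design` (or level-index matrix); must be balanced.
#' @param values Per-run numeric vector, typically S/N ratios from
#'   [snr_table()].
#' @return A `doe_anova` object: a data.frame with columns `Source`, `Df`,
#'   `SumSq`, `MeanSq`, `FValue`, `pValue` and one row per factor plus
#'   `Error` and `Total` rows. If the error mean square is zero, F is
#'   `Inf` and p is 0.
#' @examples
#' sn <- snr_table(load_fixture("table4")$EF)
#' doe_anova(l18_design(), sn)
#' @export
doe_anova <- function(design, values) {
  a <- design_assignment(design)
  n <- nrow(a)
  k <- ncol(a)
  if (length(values) != n)
    stop("values must have one entry per design run", call. = FALSE)
  bal <- check_balance(a)
  if (!bal$balanced)
    stop("design is not balanced: ", paste(bal$violations, collapse = "; "),
         call. = FALSE)
  nlev <- length(unique(as.vector(a)))
  df_factor <- nlev - 1L
  df_error <- (n - 1L) - k * df_factor
  if (df_error <= 0L)
    stop("no error degrees of freedom left (", df_error, ")", call. = FALSE)
  gm <- mean(values)
  reps <- n / nlev
  ss_factor <- vapply(seq_len(k), function(j) {
    lm <- tapply(values, a[, j], mean)
    reps * sum((lm - gm)^2)
  }, numeric(1))
  ss_total <- sum((values - gm)^2)
  ss_error <- ss_total - sum(ss_factor)
  ms_factor <- ss_factor / df_factor
  ms_error <- ss_error / df_error
  if (ms_error == 0) {
    fval <- ifelse(ms_factor > 0, Inf, NaN)
    pval <- ifelse(ms_factor > 0, 0, NaN)
  } else {
    fval <- ms_factor / ms_error
    pval <- stats::pf(fval, df_factor, df_error, lower.tail = FALSE)
  }
  tab <- data.frame(
    Source = c(colnames(a), "Error", "Total"),
    Df = c(rep(df_factor, k), df_error, n - 1L),
    SumSq = c(ss_factor, ss_error, ss_total),
    MeanSq = c(ms_factor, ms_error, NA_real_),
    FValue = c(fval, NA_real_, NA_real_),
    pValue = c(pval, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("doe_anova", "data.frame"))
}

#' @export
print.doe_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$SumSq <- sprintf("%.4f", df$SumSq)
  df$MeanSq <- ifelse(is.na(df$MeanSq), "", sprintf("%.5f", df$MeanSq))
  df$FValue <- ifelse(is.na(df$FValue), "", sprintf("%.2f", df$FValue))
  df$pValue <- ifelse(is.na(df$pValue), "", sprintf("%.3f", df$pValue))
  names(df) <- c("Source", "Degree of Freedom", "Sum of Squares",
                 "Mean Square", "F-Value", "p-Value")
  print(df, row.names = FALSE, right = TRUE)
  invisible(x)
}
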