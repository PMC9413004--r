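# Larger-the-better signal-to-noise conversion.

#' Larger-the-better signal-to-noise ratio
#'
#' The Taguchi larger-the-better S/N ratio of a set of replicate measurements,
#' \deqn{S/N = -10 \log_{10}\left(\frac{1}{n}\sum_i 1/y_i^2\right)}
#' in decibels. With a single replicate this reduces to
#' \eqn{20\log_{10}(y)}. Higher is better; only strictly positive responses
#' are admissible (the logarithm is undefined otherwise).
#'
#' @param replicates Numeric vector of one or more positive response values.
#' @return A single S/N value in dB.
#' @examples
#' snr_larger_better(98.60)        # 39.8776 dB
#' snr_larger_better(c(10, 10))    # 20 dB
#' @seealso [snr_table()] for per-run conversion of a response column.
#' @export
snr_larger_better <- function(replicates) {
  if (length(replicates) < 1L || anyNA(replicates))
    stop("at least one non-missing replicate is required", call. = FALSE)
  if (any(replicates <= 0))
    stop("larger-the-better S/N is undefined for non-positive responses",
         call. = FALSE)
  -10 * log10(mean(1 / replicates^2))
}

#' Per-run signal-to-noise conversion
#'
#' Applies [snr_larger_better()] elementwise (single replicate per run), as
#' used to convert a per-run response column - flocculation efficiency, or the
#' grey relational grade - to the decibel scale before main-effects and ANOVA
#' analysis.
#'
#' @param values Numeric vector of strictly positive per-run responses.
#' @return Numeric vector of S/N values in dB, same length and names.
#' @examples
#' snr_table(c(98.60, 97.63)) # 39.8776 39.7917
#' @export
snr_table <- function(values) {
  if (any(values <= 0) || anyNA(values))
    stop("all per-run values must be positive and non-missing", call. = FALSE)
  out <- 20 * log10(values)
  names(out) <- names(values)
  out
}
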