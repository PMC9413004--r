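# Packaged study fixtures, CSV import/export, thirds expansion.

#' Expand two-decimal triplicate means to exact thirds
#'
#' Inhibition-zone diameters recorded as triplicate means of integer-valued
#' reads print as x.33 / x.67; the underlying means are x + 1/3 and x + 2/3.
#' This helper restores the repeating-third values, leaving all other numbers
#' untouched. Working with the exact thirds reproduces the study's normalized
#' and grey relational tables to 4 decimals; with the literal 2-decimal
#' values agreement degrades to about 5e-4.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape, with `.33`/`.67` fractional parts replaced by exact
#'   thirds.
#' @examples
#' expand_thirds(c(40.33, 34.67, 35.00)) # 40.3333..., 34.6666..., 35
#' @export
expand_thirds <- function(x) {
  fr <- round(x - floor(x), 2)
  out <- x
  out[fr == 0.33] <- floor(x[fr == 0.33]) + 1 / 3
  out[fr == 0.67] <- floor(x[fr == 0.67]) + 2 / 3
  out
}

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "taguchigra")
  if (p == "") stop("fixture file not found: ", file, call. = FALSE)
  p
}

#' Load a packaged study fixture
#'
#' The study's printed tables ship with the package as plain-text fixtures:
#' \describe{
#'   \item{`"design"`}{the L18 design, as a [l18_design()] object.}
#'   \item{`"factors"`}{factor metadata, as [taguchi_factors()].}
#'   \item{`"table4"`}{18 flocculation efficiencies (%) with the published
#'     S/N column, as a data.frame `run, EF, SN`.}
#'   \item{`"table6"`}{the 18 x 5 multi-response matrix (efficiency % plus
#'     four inhibition-zone diameters, mm), as a data.frame with a `run`
#'     column.}
#'   \item{`"table10"`}{the validation run's five responses (one row, same
#'     schema as `"table6"`).}
#' }
#'
#' @param name One of `"design"`, `"factors"`, `"table4"`, `"table6"`,
#'   `"table10"`.
#' @param thirds Expand `.33`/`.67` zone values to exact thirds via
#'   [expand_thirds()] (default `TRUE`; applies to zone columns of
#'   `"table6"` and `"table10"` only).
#' @return See above.
#' @examples
#' head(load_fixture("table6", thirds = FALSE), 1) # run 1: 98.60, 42.00, ...
#' @export
load_fixture <- function(name, thirds = TRUE) {
  known <- c("design", "factors", "table4", "table6", "table10")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    stop("unknown fixture ", sQuote(name), "; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  switch(name,
    design = l18_design(load_fixture("factors")),
    factors = {
      raw <- jsonlite::read_json(.fixture_path("factors.json"),
                                 simplifyVector = TRUE)
      lapply(seq_len(nrow(raw)), function(i)
        list(notation = raw$notation[i], name = raw$name[i],
             unit = raw$unit[i], levels = unlist(raw$levels[i])))
    },
    table4 = utils::read.csv(.fixture_path("table4_ef.csv")),
    table6 = {
      df <- read_response_csv(.fixture_path("table6_responses.csv"))
      if (thirds) df[-(1:2)] <- lapply(df[-(1:2)], expand_thirds)
      df
    },
    table10 = {
      df <- read_response_csv(.fixture_path("table10_validation.csv"))
      if (thirds) df[-(1:2)] <- lapply(df[-(1:2)], expand_thirds)
      df
    }
  )
}

#' Read a response-matrix CSV
#'
#' Expects a header `run,<response names...>` with one row per run. Rows may
#' arrive out of order; they are sorted by run id. Parse failures name the
#' offending row.
#'
#' @param path CSV file path.
#' @param responses Optional required response names (schema check).
#' @return A data.frame with a `run` column followed by numeric response
#'   columns.
#' @export
read_response_csv <- function(path, responses = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (!"run" %in% names(df))
    stop("missing 'run' column in ", path, call. = FALSE)
  if (!is.null(responses)) {
    missing_cols <- setdiff(responses, names(df))
    if (length(missing_cols))
      stop("missing response column(s) in ", path, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # normalize unicode minus signs, then parse numerics with row diagnostics
  for (col in names(df)) {
    vals <- gsub("\u2212", "-", df[[col]])
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | !nzchar(vals))
    if (length(bad))
      stop("non-numeric or blank value in column '", col, "', row ",
           bad[1], " of ", path, call. = FALSE)
    df[[col]] <- num
  }
  if (anyDuplicated(df$run))
    stop("duplicate run id(s) in ", path, ": ",
         paste(unique(df$run[duplicated(df$run)]), collapse = ", "),
         call. = FALSE)
  df <- df[order(df$run), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_response_csv()]: writes `run,<responses...>` such that
#' reading the file back reproduces the input exactly.
#'
#' @param x Data.frame with a `run` column, or a runs x responses matrix
#'   (row names become run ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(x, path) {
  if (!is.data.frame(x)) {
    m <- as_response_matrix(x)
    x <- data.frame(run = rownames(m), m, check.names = FALSE,
                    row.names = NULL)
    x$run <- utils::type.convert(x$run, as.is = TRUE)
  }
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
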