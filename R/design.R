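# L18(3^5) orthogonal design, combination labels, balance checks, and the
# raw flocculation-efficiency metric.

# The 18 runs of the study design, one combination label per run. Stored
# explicitly (the study fixes this particular column selection); generating
# generic L18 catalogues is out of scope.
.l18_labels <- c(
  "A_1_B_1_C_1_D_1_E_1_", "A_1_B_2_C_2_D_2_E_2_", "A_1_B_3_C_3_D_3_E_3_",
  "A_2_B_1_C_1_D_2_E_2_", "A_2_B_2_C_2_D_3_E_3_", "A_2_B_3_C_3_D_1_E_1_",
  "A_3_B_1_C_2_D_1_E_3_", "A_3_B_2_C_3_D_2_E_1_", "A_3_B_3_C_1_D_3_E_2_",
  "A_1_B_1_C_3_D_3_E_2_", "A_1_B_2_C_1_D_1_E_3_", "A_1_B_3_C_2_D_2_E_1_",
  "A_2_B_1_C_2_D_3_E_1_", "A_2_B_2_C_3_D_1_E_2_", "A_2_B_3_C_1_D_2_E_3_",
  "A_3_B_1_C_3_D_2_E_3_", "A_3_B_2_C_1_D_3_E_1_", "A_3_B_3_C_2_D_1_E_2_"
)

#' Factor specifications of the flocculation study
#'
#' The five controllable factors of the case study, each at three levels:
#' chitosan type (three commercial chitosans differing in molecular mass and
#' degree of deacetylation), pH, chitosan dosage (mg/L), rapid mixing speed
#' (rpm) and slow mixing speed (rpm). Physical level values are metadata only;
#' all arithmetic uses 1-based level indices.
#'
#' @return A list of five factor specifications, each a list with elements
#'   `notation` (single letter A-E), `name`, `unit` (may be `""`) and
#'   `levels` (character vector of length 3 with the physical level values).
#' @examples
#' taguchi_factors()[[3]]$levels # dosage levels in mg/L
#' @export
taguchi_factors <- function() {
  list(
    list(notation = "A", name = "chitosan type", unit = "",
         levels = c("ch1", "ch2", "ch3")),
    list(notation = "B", name = "pH value", unit = "",
         levels = c("5", "6", "7")),
    list(notation = "C", name = "chitosan dosage", unit = "mg/L",
         levels = c("45", "55", "65")),
    list(notation = "D", name = "rapid mixing", unit = "rpm",
         levels = c("250", "350", "450")),
    list(notation = "E", name = "slow mixing", unit = "rpm",
         levels = c("50", "100", "150"))
  )
}

validate_factors <- function(factors) {
  stopifnot(is.list(factors), length(factors) >= 1)
  notation <- vapply(factors, function(f) f$notation, character(1))
  if (anyDuplicated(notation))
    stop("factor notations must be unique, got: ",
         paste(notation, collapse = ", "), call. = FALSE)
  nlev <- vapply(factors, function(f) length(f$levels), integer(1))
  if (any(nlev != 3L))
    stop("every factor must have exactly 3 levels", call. = FALSE)
  invisible(factors)
}

new_taguchi_design <- function(assignment, factors) {
  validate_factors(factors)
  assignment <- as.matrix(assignment)
  storage.mode(assignment) <- "integer"
  colnames(assignment) <- vapply(factors, function(f) f$notation, character(1))
  rownames(assignment) <- as.character(seq_len(nrow(assignment)))
  if (any(assignment < 1L | assignment > 3L))
    stop("level indices must lie in {1, 2, 3}", call. = FALSE)
  structure(list(assignment = assignment, factors = factors),
            class = "taguchi_design")
}

#' The L18 orthogonal design of the flocculation study
#'
#' Returns the exact 18-run, five-factor, three-level orthogonal array used by
#' the study (run 1 = A1B1C1D1E1, ..., run 18 = A3B3C2D1E2). Every factor
#' column contains each level exactly 6 times, and every pair of factor
#' columns contains each of the 9 level pairs exactly twice
#' (see [check_balance()]).
#'
#' @param factors Factor metadata, defaulting to [taguchi_factors()].
#' @return A `taguchi_design` object: a list with `assignment` (18 x 5 integer
#'   matrix of level indices, columns named A-E) and `factors`.
#' @examples
#' des <- l18_design()
#' des$assignment[13, ] # run 13 is A2 B1 C2 D3 E1
#' @seealso [parse_combination()], [check_balance()]
#' @export
l18_design <- function(factors = taguchi_factors()) {
  assignment <- t(vapply(.l18_labels, parse_combination, integer(5)))
  rownames(assignment) <- NULL
  new_taguchi_design(assignment, factors)
}

#' @export
print.taguchi_design <- function(x, ...) {
  cat(sprintf("Taguchi design: %d runs, %d factors (%s)\n",
              nrow(x$assignment), ncol(x$assignment),
              paste(colnames(x$assignment), collapse = "")))
  labs <- apply(x$assignment, 1, format_combination)
  df <- data.frame(run = seq_along(labs), combination = labs,
                   x$assignment, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Parse a parameter-combination label
#'
#' Converts a label of the form `"A_3_B_1_C_2_D_1_E_3_"` (underscores and
#' whitespace optional, so `"A3B1C2D1E3"` is also accepted) into the vector of
#' five level indices. Inverse of [format_combination()].
#'
#' @param label A single character string naming factors A-E in order, each
#'   followed by a level digit 1-3.
#' @return Integer vector of length 5 with names `A`-`E`.
#' @examples
#' parse_combination("A_3_B_1_C_2_D_1_E_3_") # 3 1 2 1 3
#' @export
parse_combination <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  clean <- gsub("[_[:space:]]", "", label)
  tokens <- regmatches(clean, gregexpr("[A-Za-z][0-9]*", clean))[[1]]
  if (length(tokens) == 0L || nchar(paste(tokens, collapse = "")) != nchar(clean))
    stop("malformed combination label: ", sQuote(label), call. = FALSE)
  expected <- LETTERS[1:5]
  if (length(tokens) != 5L)
    stop("combination label must contain the five factors A-E, got ",
         length(tokens), " token(s) in ", sQuote(label), call. = FALSE)
  out <- integer(5)
  for (i in seq_len(5L)) {
    tok <- tokens[i]
    letter <- substr(tok, 1, 1)
    digit <- substr(tok, 2, nchar(tok))
    if (letter != expected[i])
      stop("expected factor ", expected[i], " but found token ", sQuote(tok),
           " in ", sQuote(label), call. = FALSE)
    if (!grepl("^[1-3]$", digit))
      stop("level digit outside 1-3 in token ", sQuote(tok),
           " of ", sQuote(label), call. = FALSE)
    out[i] <- as.integer(digit)
  }
  names(out) <- expected
  out
}

#' Format a level combination as a label
#'
#' @param levels Integer vector of length 5 with level indices in 1-3.
#' @return A label of the form `"A_3_B_1_C_2_D_1_E_3_"`, matching the printed
#'   run labels of the study.
#' @examples
#' format_combination(c(3, 1, 2, 1, 3))
#' @export
format_combination <- function(levels) {
  levels <- as.integer(levels)
  stopifnot(length(levels) == 5L, !anyNA(levels), all(levels %in% 1:3))
  paste0(paste0(LETTERS[1:5], "_", levels, "_"), collapse = "")
}

#' Check level and pairwise balance of a design
#'
#' An orthogonal array of strength 2 has each level appearing equally often in
#' every factor column, and each of the 9 ordered level pairs appearing
#' equally often in every pair of columns. Both properties are verified by
#' exhaustive counting.
#'
#' @param design A `taguchi_design`, or a matrix/data.frame of level indices
#'   (runs x factors).
#' @return A `balance_report` list: `level_counts` (3 x k matrix),
#'   `pair_counts` (named list of 3 x 3 matrices, one per factor pair),
#'   `balanced` (single logical), and `violations` (character vector
#'   describing any unbalanced factor or pair).
#' @examples
#' check_balance(l18_design())$balanced # TRUE
#' @export
check_balance <- function(design) {
  a <- design_assignment(design)
  if (ncol(a) < 2L) stop("balance check needs at least 2 factors", call. = FALSE)
  fac <- colnames(a)
  lev <- 1:3 # level indices are contractually in {1, 2, 3}
  level_counts <- matrix(0L, length(lev), ncol(a),
                         dimnames = list(level = lev, factor = fac))
  for (j in seq_len(ncol(a)))
    level_counts[, j] <- tabulate(match(a[, j], lev), length(lev))
  violations <- character(0)
  if (length(unique(as.vector(level_counts))) != 1L) {
    bad <- fac[apply(level_counts, 2, function(cc) length(unique(cc)) != 1L)]
    violations <- c(violations, paste0("unequal level counts in factor ",
                                       bad))
  }
  pair_counts <- list()
  for (i in seq_len(ncol(a) - 1L)) {
    for (j in seq((i + 1L), ncol(a))) {
      tab <- table(factor(a[, i], levels = lev), factor(a[, j], levels = lev))
      key <- paste0(fac[i], fac[j])
      pair_counts[[key]] <- unclass(tab)
      if (length(unique(as.vector(tab))) != 1L)
        violations <- c(violations,
                        paste0("unequal pair counts for factors ", key))
    }
  }
  structure(list(level_counts = level_counts, pair_counts = pair_counts,
                 balanced = length(violations) == 0L,
                 violations = violations),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Design balance:", if (x$balanced) "balanced" else "NOT balanced", "\n")
  cat("Level counts per factor:\n")
  print(x$level_counts)
  if (!x$balanced) cat("Violations:\n ", paste(x$violations, collapse = "\n  "), "\n")
  invisible(x)
}

# Accept a taguchi_design, matrix or data.frame and return the integer
# assignment matrix with factor-letter column names.
design_assignment <- function(design) {
  if (inherits(design, "taguchi_design")) return(design$assignment)
  a <- as.matrix(design)
  storage.mode(a) <- "integer"
  if (is.null(colnames(a))) colnames(a) <- LETTERS[seq_len(ncol(a))]
  a
}

#' Flocculation efficiency from optical densities
#'
#' The percentage drop in optical density at 600 nm of a microbial suspension
#' after flocculant addition and settling:
#' \deqn{EF = 100 (OD_0 - OD) / OD_0}
#' where \eqn{OD_0} and \eqn{OD} are the optical densities before and after
#' treatment. Negative values (the suspension got denser) are allowed and
#' signal failed flocculation; no floor is imposed.
#'
#' @param od_before Optical density before flocculation (must be positive).
#' @param od_after Optical density after flocculation (non-negative).
#' @return Efficiency in percent, at most 100. Vectorized.
#' @examples
#' flocculation_efficiency(0.5, 0.25) # 50
#' @export
flocculation_efficiency <- function(od_before, od_after) {
  if (any(!is.finite(od_before)) || any(od_before <= 0))
    stop("od_before must be strictly positive", call. = FALSE)
  if (any(!is.finite(od_after)) || any(od_after < 0))
    stop("od_after must be non-negative", call. = FALSE)
  100 * (od_before - od_after) / od_before
}
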