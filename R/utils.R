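`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero to integer
#'
#' Commercial ("half-up") rounding: 62.5 rounds to 63, 12.5 to 13. Used for
#' cohort benefit percentages, where base R's round-half-even would print 62
#' for 5/8.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

TERNARY <- c("yes", "no", "unknown")

#' @noRd
as_ternary <- function(x, field = "flag") {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws(as.character(x)))) {
    return("unknown")
  }
  x <- tolower(trimws(as.character(x)))
  if (x %in% c("n/a", "na", "(-)")) return("unknown")
  if (x %in% c("true", "y")) x <- "yes"
  if (x %in% c("false", "n")) x <- "no"
  if (!x %in% TERNARY) {
    stop(sprintf("field '%s': expected yes/no/unknown, got '%s'", field, x),
         call. = FALSE)
  }
  x
}

is_yes <- function(x) identical(x, "yes")

# Interval membership with open/closed bounds. An infinite bound means
# unbounded on that side, so `Inf` ("not reached") satisfies any lower bound
# and fails only finite upper bounds.
in_interval <- function(x, lower, lower_closed, upper, upper_closed) {
  lo <- if (is.infinite(lower) && lower < 0) TRUE
        else if (lower_closed) x >= lower else x > lower
  hi <- if (is.infinite(upper) && upper > 0) TRUE
        else if (upper_closed) x <= upper else x < upper
  lo && hi
}

# Parse one scalar cell from a CSV/JSON record. Handles the explicit missing
# token "(-)", empty cells, the "not reached" duration token (-> Inf) and
# middle-dot decimals.
parse_cell_number <- function(x, field = "value") {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(NA_real_)
  if (is.numeric(x)) return(as.double(x))
  x <- trimws(as.character(x))
  if (!nzchar(x) || x %in% c("(-)", "n/a", "NA")) return(NA_real_)
  if (tolower(x) %in% c("not reached", "nr")) return(Inf)
  x <- gsub("·", ".", x)
  x <- gsub("−", "-", x)  # unicode minus
  x <- gsub("%$", "", x)
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val)) {
    stop(sprintf("field '%s': cannot parse numeric value from '%s'", field, x),
         call. = FALSE)
  }
  val
}

format_cell_number <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return("")
  if (is.infinite(x)) return("not reached")
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

compact <- function(x) x[!vapply(x, is.null, logical(1))]
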