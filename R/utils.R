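# Shared helpers: month calendars, numeric parsing, small statistics.

#' Default month calendar
#'
#' The sampling calendar used throughout the package: an ordered sequence of
#' month labels starting in November and ending in September, covering the
#' eight months with non-empty medusa collections. Grouped summaries and
#' plots present months in this order rather than calendar-year order.
#'
#' @return Character vector of ordered month labels.
#' @export
#' @examples
#' paper_months()
paper_months <- function() {
  c("Nov", "Dec", "Feb", "Apr", "May", "Jun", "Jul", "Sep")
}

#' Coerce month labels to an ordered factor
#'
#' @param x Character or factor vector of month labels.
#' @param months Ordered label set; defaults to [paper_months()].
#' @return Ordered factor with levels `months`.
#' @export
as_month <- function(x, months = paper_months()) {
  bad <- setdiff(unique(as.character(x)), months)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown month label(s): %s (calendar: %s)",
      paste(bad, collapse = ", "), paste(months, collapse = ", ")
    ))
  }
  factor(as.character(x), levels = months, ordered = TRUE)
}

# Normalize Unicode minus (U+2212) and stray whitespace, then parse numerics.
# Returns NA for unparseable entries; callers decide whether NA is an error.
parse_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("−", "-", as.character(x))
  x <- trimws(x)
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

# Round half away from zero (common "half-up" convention for pseudo-counts;
# base round() is banker's rounding).
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Mean and standard error of a numeric vector. A single observation has no
# sample SD; report SE = 0 and flag it so downstream tables can annotate.
mean_se <- function(x) {
  n <- length(x)
  if (n == 0L) abort("mean_se(): empty vector")
  if (n == 1L) {
    tibble(mean = x, se = 0, n = 1L, se_defined = FALSE)
  } else {
    tibble(mean = mean(x), se = sd(x) / sqrt(n), n = n, se_defined = TRUE)
  }
}

# Derive a reproducible child seed from a base seed and an index, staying
# within 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}
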