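`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a percent-or-fraction value
#'
#' User files mix notations for the same quantity: `"40%"`, `"40"` and `"0.40"`
#' all mean the fraction 0.40. The rule is: a trailing `%` always marks a
#' percent; otherwise numeric values greater than 1 are percents and values in
#' \code{[0, 1]} are fractions.
#'
#' @param x character or numeric vector.
#' @return numeric vector of fractions.
#' @examples
#' parse_fraction(c("40%", "40", "0.40", "+100%"))
#' @export
parse_fraction <- function(x) {
  if (is.character(x)) {
    x <- trimws(x)
    pct <- grepl("%$", x)
    num <- suppressWarnings(as.numeric(sub("%$", "", sub("^\\+", "", x))))
    if (anyNA(num)) {
      stop("non-numeric value(s): ", paste(x[is.na(num)], collapse = ", "),
           call. = FALSE)
    }
    ifelse(pct, num / 100, ifelse(num > 1, num / 100, num))
  } else {
    ifelse(x > 1, x / 100, x)
  }
}

#' Display a fraction as a percent, rounded half-up
#'
#' Weights are kept at full precision internally; reports print them as
#' percents rounded half-up to a fixed number of decimals (so 0.125265 prints
#' as 12.5 and 0.18790 as 18.8). Base \code{round()} rounds half to even,
#' which does not reproduce the conventional table formatting.
#'
#' @param x fraction(s) in \code{[0, 1]}.
#' @param digits decimal places of the percent (default 1).
#' @return numeric percent value(s).
#' @export
percent_display <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * 100 * m + 0.5) / m
}

# Snap a value to the nearest grid point; exact midpoints snap downward.
# Grids are short, so a linear scan is fine.
snap_to_grid <- function(x, grid) {
  grid <- sort(grid)
  d <- abs(grid - x)
  i <- which(d <= min(d) + 1e-12)[1L]  # first index = lower value on ties
  grid[i]
}

# Match values against a grid with floating-point tolerance; NA where off-grid.
grid_match <- function(x, grid, tol = 1e-9) {
  vapply(x, function(v) {
    i <- which(abs(grid - v) <= tol)
    if (length(i)) grid[i[1L]] else NA_real_
  }, numeric(1))
}
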