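# Internal helpers shared across modules.

# Absolute ceiling on clutch size: up to 7 offspring per host have been
# observed under extreme conditions, even though routine clutches are 1-4.
MAX_CLUTCH_ABS <- 7L

#' Round half away from zero
#'
#' Reporting-layer rounding used throughout the package (cohort fertilities,
#' relative efficiencies, percent changes). Unlike [base::round()], which
#' rounds half to even, halves are rounded away from zero, so 0.5 -> 1 and
#' -0.5 -> -1.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_clutchfit <- function(msg, class) {
  stop(structure(
    class = c(class, "clutchfit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is_count(x, min)) {
    stop_clutchfit(
      sprintf("`%s` must be a single integer >= %d (got %s)",
              name, min, paste(utils::head(x, 3), collapse = ", ")),
      "clutchfit_invalid_input"
    )
  }
  as.integer(x)
}
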