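#' Wing-length to fertility regression line
#'
#' Holds the intercept and slope of the linear body-size/fertility map
#' (eggs as a function of wing length in mm). Predicted fertilities are
#' clipped at zero: an egg complement cannot be negative.
#'
#' @param intercept Intercept in eggs.
#' @param slope Slope in eggs per mm of wing length.
#' @param se Optional length-2 numeric: standard errors of intercept and
#'   slope (from a fitted model).
#' @param r_squared Optional coefficient of determination.
#' @param n Optional number of observations behind the fit.
#' @return An object of class `regression_line`.
#' @seealso [predict_fertility()], [fit_wing_fertility()]
#' @export
regression_line <- function(intercept, slope, se = c(NA_real_, NA_real_),
                            r_squared = NA_real_, n = NA_integer_) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept) ||
      !is.numeric(slope) || length(slope) != 1L || !is.finite(slope)) {
    stop_clutchfit("intercept and slope must be single finite numbers",
                   "clutchfit_invalid_input")
  }
  structure(
    list(intercept = as.numeric(intercept), slope = as.numeric(slope),
         se = as.numeric(se), r_squared = r_squared, n = n),
    class = "regression_line"
  )
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("<regression_line> fertility = %.4g + %.4g * wing_length_mm\n",
              x$intercept, x$slope))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.3f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' Predict hypothetical fertility from wing length
#'
#' Applies the regression line to one or more wing lengths and clips at
#' zero. This is the "hypothetical fertility" of a female: the egg
#' complement her body size implies, whether or not she ever lays it.
#'
#' @param line A [regression_line].
#' @param wing_length Wing length(s) in mm; must be finite and positive.
#' @return Predicted fertility in eggs, `>= 0`, same length as `wing_length`.
#' @export
#' @examples
#' predict_fertility(regression_line(2, 30), 0.5)
predict_fertility <- function(line, wing_length) {
  stopifnot(inherits(line, "regression_line"))
  if (!is.numeric(wing_length) || length(wing_length) < 1L ||
      any(!is.finite(wing_length)) || any(wing_length <= 0)) {
    stop_clutchfit("`wing_length` must be finite and positive",
                   "clutchfit_invalid_input")
  }
  pmax(0, line$intercept + line$slope * wing_length)
}

#' Clutch composition: one host's clutch split by sex
#'
#' @param size Clutch size (offspring laid in the host), `1..7`.
#' @param n_females Number of female offspring, `0..size`.
#' @return An object of class `clutch_composition` with fields `size`,
#'   `n_females`, `n_males`.
#' @export
#' @examples
#' clutch_composition(3, n_females = 2)
clutch_composition <- function(size, n_females) {
  size <- check_count(size, "size", min = 1L)
  n_females <- check_count(n_females, "n_females", min = 0L)
  if (size > MAX_CLUTCH_ABS) {
    stop_clutchfit(sprintf("clutch size %d exceeds the absolute maximum %d",
                           size, MAX_CLUTCH_ABS),
                   "clutchfit_invalid_input")
  }
  if (n_females > size) {
    stop_clutchfit("n_females cannot exceed clutch size", "clutchfit_invalid_input")
  }
  structure(list(size = size, n_females = n_females, n_males = size - n_females),
            class = "clutch_composition")
}

#' A host egg slot: host type plus (possibly empty) clutch
#'
#' @param host_type `"native"` or `"non_native"`. Non-native hosts accept
#'   oviposition but parasitoid larvae cannot complete development in them:
#'   they yield zero emerged offspring and zero F2, while still consuming
#'   the eggs laid there.
#' @param composition A [clutch_composition], or `NULL` for an
#'   unparasitised host.
#' @return An object of class `host_slot`.
#' @export
host_slot <- function(host_type = c("native", "non_native"), composition = NULL) {
  host_type <- match.arg(host_type)
  if (!is.null(composition) && !inherits(composition, "clutch_composition")) {
    stop_clutchfit("`composition` must be a clutch_composition or NULL",
                   "clutchfit_invalid_input")
  }
  structure(list(host_type = host_type, composition = composition),
            class = "host_slot")
}

#' An allocation of clutches over an ordered set of hosts
#'
#' @param slots A list of [host_slot] objects.
#' @return An object of class `allocation`.
#' @seealso [native_allocation()], [allocation_f2()], [f1_count()]
#' @export
allocation <- function(slots = list()) {
  if (!is.list(slots) || !all(vapply(slots, inherits, logical(1), "host_slot"))) {
    stop_clutchfit("`slots` must be a list of host_slot objects",
                   "clutchfit_invalid_input")
  }
  structure(list(slots = slots), class = "allocation")
}

#' Build an all-native allocation from clutch sizes
#'
#' Convenience constructor for the common case: every listed host is native
#' and parasitised. By default every offspring is female (the all-female
#' accounting under which per-host F2 equals `k * f(k)`).
#'
#' @param sizes Integer vector of clutch sizes, one per parasitised host.
#' @param n_females Females per clutch; defaults to `sizes` (all-female).
#' @param n_empty Number of additional unparasitised native hosts.
#' @return An [allocation].
#' @export
#' @examples
#' native_allocation(c(2, 2, 2))
native_allocation <- function(sizes, n_females = sizes, n_empty = 0L) {
  sizes <- vapply(sizes, check_count, integer(1), name = "sizes", min = 1L)
  if (length(n_females) != length(sizes)) {
    stop_clutchfit("`n_females` must match `sizes` in length", "clutchfit_invalid_input")
  }
  slots <- c(
    mapply(function(k, nf) host_slot("native", clutch_composition(k, nf)),
           sizes, n_females, SIMPLIFY = FALSE),
    replicate(check_count(n_empty, "n_empty"), host_slot("native"), simplify = FALSE)
  )
  allocation(slots)
}

#' Expected F2 fertility contributed by one host
#'
#' The clutch-size-specific hypothetical fertility of a single female
#' offspring, multiplied by the number of female offspring in the host.
#' Male fertility is zero in this accounting, so males contribute nothing.
#'
#' @param table A [fertility_table].
#' @param comp A [clutch_composition].
#' @return F2 eggs (`>= 0`) obtainable from this host's offspring.
#' @export
#' @examples
#' per_host_f2(default_fertility_table(), clutch_composition(2, 2))
per_host_f2 <- function(table, comp) {
  stopifnot(inherits(comp, "clutch_composition"))
  comp$n_females * fertility_of(table, comp$size)
}

#' Total F2 fertility of an allocation
#'
#' Sums [per_host_f2()] over parasitised native slots. Non-native slots
#' contribute zero (their offspring never complete development); an empty
#' allocation yields zero.
#'
#' @param table A [fertility_table].
#' @param alloc An [allocation].
#' @return Total F2 eggs.
#' @export
allocation_f2 <- function(table, alloc) {
  stopifnot(inherits(alloc, "allocation"))
  total <- 0
  for (slot in alloc$slots) {
    if (slot$host_type == "native" && !is.null(slot$composition)) {
      total <- total + per_host_f2(table, slot$composition)
    }
  }
  total
}

#' Emerged F1 offspring and eggs laid for an allocation
#'
#' F1 fertility in the traditional sense is the count of emerged offspring:
#' only clutches in native hosts emerge. Eggs laid additionally counts
#' clutches deposited in non-native hosts (they deplete the egg budget but
#' produce nothing).
#'
#' @param alloc An [allocation].
#' @return A list with `f1_emerged` and `eggs_laid` (integer counts).
#' @export
f1_count <- function(alloc) {
  stopifnot(inherits(alloc, "allocation"))
  f1 <- 0L
  laid <- 0L
  for (slot in alloc$slots) {
    if (!is.null(slot$composition)) {
      laid <- laid + slot$composition$size
      if (slot$host_type == "native") f1 <- f1 + slot$composition$size
    }
  }
  list(f1_emerged = f1, eggs_laid = laid)
}

#' F2 fertility of a cohort of offspring sharing one clutch size
#'
#' `n_offspring * f(clutch)`: the total egg complement of `n_offspring`
#' (all-female) individuals that each developed in a clutch of the given
#' size. With `report_rounding = TRUE` the value is rounded to the nearest
#' integer (half away from zero), the form used in reporting tables.
#'
#' @param table A [fertility_table].
#' @param clutch Clutch size the cohort developed in.
#' @param n_offspring Cohort size (`>= 0`).
#' @param report_rounding Round the result for reporting?
#' @return F2 eggs.
#' @export
#' @examples
#' cohort_f2(default_fertility_table(), clutch = 1, n_offspring = 12,
#'           report_rounding = TRUE)
cohort_f2 <- function(table, clutch, n_offspring, report_rounding = FALSE) {
  n_offspring <- check_count(n_offspring, "n_offspring")
  out <- n_offspring * fertility_of(table, clutch)
  if (report_rounding) round_half_away(out) else out
}

#' Relative F2 efficiency of a clutch size against clutch size 1
#'
#' The ratio of the rounded cohort F2 at clutch size `clutch` to the
#' rounded cohort F2 at clutch size 1, expressed as a percentage rounded to
#' the nearest percent. Rounding the cohort values first (then taking the
#' ratio) is the canonical order.
#'
#' @inheritParams cohort_f2
#' @return Integer percentage.
#' @export
#' @examples
#' relative_efficiency(default_fertility_table(), clutch = 2, n_offspring = 12)
relative_efficiency <- function(table, clutch, n_offspring) {
  base <- cohort_f2(table, 1L, n_offspring, report_rounding = TRUE)
  if (base == 0) {
    stop_clutchfit("relative efficiency undefined: clutch-1 cohort fertility is zero",
                   "clutchfit_invalid_input")
  }
  value <- cohort_f2(table, clutch, n_offspring, report_rounding = TRUE)
  as.integer(round_half_away(100 * value / base))
}

#' Clutch-size fertility summary table
#'
#' One row per clutch size: per-offspring fertility, all-female per-host
#' fertility `k * f(k)`, the rounded fertility of an `n_offspring` cohort,
#' and its relative efficiency against clutch size 1.
#'
#' @param table A [fertility_table].
#' @param n_offspring Cohort size for the cohort column (default 12, one
#'   full host complement at 12 hosts parasitised singly).
#' @return A data frame with columns `clutch_size`, `per_offspring_fertility`,
#'   `per_host_all_female`, `cohort_fertility`, `efficiency_pct`.
#' @export
#' @examples
#' fertility_summary(default_fertility_table())
fertility_summary <- function(table, n_offspring = 12L) {
  stopifnot(inherits(table, "fertility_table"))
  k <- seq_len(table$max_clutch)
  data.frame(
    clutch_size = k,
    per_offspring_fertility = unname(table$f),
    per_host_all_female = k * unname(table$f),
    cohort_fertility = vapply(k, function(kk)
      cohort_f2(table, kk, n_offspring, report_rounding = TRUE), numeric(1)),
    efficiency_pct = vapply(k, function(kk)
      relative_efficiency(table, kk, n_offspring), integer(1))
  )
}
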