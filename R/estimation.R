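# The two-step statistical procedure: (1) ordinary least squares of
# maternal fertility on wing length; (2) clutch-size-specific hypothetical
# fertilities obtained by pushing offspring wing lengths through the fitted
# line, averaged over female offspring (male fertility is zero by
# definition in this accounting). Group comparisons are reported as
# descriptive means with confidence intervals only; mixed-model inference
# is deliberately left to external tools.

#' Fit the wing-length to fertility regression
#'
#' Ordinary least squares of realised fertility (egg count) on wing length
#' (mm) across mother records. Both variables are treated as normally
#' distributed continuous measurements.
#'
#' @param mothers Data frame with columns `wing_length_mm` and `fertility`
#'   (and typically `mother_id`, `n_hosts`); at least 3 rows with at least
#'   2 distinct wing lengths.
#' @return A [regression_line] carrying intercept/slope standard errors,
#'   `r_squared` and `n`.
#' @export
#' @examples
#' mothers <- data.frame(wing_length_mm = c(0.5, 0.6, 0.7),
#'                       fertility = 2 + 30 * c(0.5, 0.6, 0.7))
#' fit_wing_fertility(mothers)
fit_wing_fertility <- function(mothers) {
  req <- c("wing_length_mm", "fertility")
  missing_cols <- setdiff(req, names(mothers))
  if (length(missing_cols)) {
    stop_clutchfit(sprintf("mother records: missing column(s) %s",
                           paste(missing_cols, collapse = ", ")),
                   "clutchfit_validation")
  }
  if (nrow(mothers) < 3L) {
    stop_clutchfit("at least 3 mother records are required to fit the regression",
                   "clutchfit_validation")
  }
  if (length(unique(mothers$wing_length_mm)) < 2L) {
    stop_clutchfit("singular fit: all wing lengths are identical",
                   "clutchfit_singular_fit")
  }
  fit <- stats::lm(fertility ~ wing_length_mm, data = mothers)
  s <- summary(fit)
  regression_line(
    intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L]),
    se = unname(s$coefficients[, "Std. Error"]),
    r_squared = s$r.squared,
    n = nrow(mothers)
  )
}

#' Build a fertility table from offspring records and a fitted line
#'
#' For each clutch size `k`, the per-offspring fertility `f(k)` is the mean
#' hypothetical fertility ([predict_fertility()]) over FEMALE offspring
#' that developed in clutches of size `k` (males carry no fertility in
#' this model), and `mean_females_per_host(k)` is the mean number of
#' female offspring among hosts with that clutch size. Clutch sizes absent
#' from the data, or observed with no female offspring, yield `NA` entries
#' and an incomplete table.
#'
#' @param offspring Data frame with columns `host_id`, `clutch_size`, `sex`
#'   (`"F"`/`"M"`) and `wing_length_mm`. Each host's `clutch_size` must
#'   equal its number of offspring records.
#' @param line A [regression_line].
#' @param max_clutch Largest clutch size the table should cover.
#' @return A [fertility_table] (possibly flagged incomplete).
#' @export
build_fertility_table <- function(offspring, line, max_clutch = 4L) {
  req <- c("host_id", "clutch_size", "sex", "wing_length_mm")
  missing_cols <- setdiff(req, names(offspring))
  if (length(missing_cols)) {
    stop_clutchfit(sprintf("offspring records: missing column(s) %s",
                           paste(missing_cols, collapse = ", ")),
                   "clutchfit_validation")
  }
  max_clutch <- check_count(max_clutch, "max_clutch", min = 1L)
  if (!all(offspring$sex %in% c("F", "M"))) {
    stop_clutchfit("offspring sex must be coded F/M", "clutchfit_validation")
  }
  counts <- table(offspring$host_id)
  declared <- tapply(offspring$clutch_size, offspring$host_id, function(x) x[1L])
  inconsistent <- names(counts)[counts != declared[names(counts)]]
  mixed <- tapply(offspring$clutch_size, offspring$host_id,
                  function(x) length(unique(x)) > 1L)
  inconsistent <- union(inconsistent, names(mixed)[mixed])
  if (length(inconsistent)) {
    stop_clutchfit(
      sprintf("clutch_size inconsistent with offspring counts for host(s) %s",
              paste(utils::head(inconsistent, 5), collapse = ", ")),
      "clutchfit_validation"
    )
  }

  f <- rep(NA_real_, max_clutch)
  mf <- rep(NA_real_, max_clutch)
  for (k in seq_len(max_clutch)) {
    at_k <- offspring[offspring$clutch_size == k, , drop = FALSE]
    if (nrow(at_k) == 0L) next
    fem <- at_k[at_k$sex == "F", , drop = FALSE]
    if (nrow(fem) > 0L) {
      f[k] <- mean(predict_fertility(line, fem$wing_length_mm))
    }
    fem_per_host <- tapply(at_k$sex == "F", at_k$host_id, sum)
    mf[k] <- mean(fem_per_host)
  }
  out <- fertility_table(f, mean_females_per_host = mf, incomplete = anyNA(f))
  attr(out, "observed_clutch_sizes") <-
    sort(unique(offspring$clutch_size[offspring$clutch_size <= max_clutch]))
  out
}

#' Mean with a 95% confidence interval
#'
#' `method = "normal"` gives the t-interval
#' `mean +/- t(0.975, n - 1) * sd / sqrt(n)` (for `n = 1` the bounds are
#' `NA`). `method = "poisson"` treats the values as counts and returns the
#' exact chi-square interval for the mean of a Poisson sample: with total
#' `S` over `n` observations, the bounds are `qchisq(0.025, 2S) / (2n)`
#' (0 when `S = 0`) and `qchisq(0.975, 2(S + 1)) / (2n)`.
#'
#' @param values Numeric vector; for the Poisson method, non-negative
#'   integers.
#' @param method `"normal"` or `"poisson"`.
#' @return A list with `mean`, `ci_low`, `ci_high`, `n`, `method`.
#' @export
#' @examples
#' summarize_ci(c(1, 2, 3, 4, 5))
#' summarize_ci(c(0, 1, 3), method = "poisson")
summarize_ci <- function(values, method = c("normal", "poisson")) {
  method <- match.arg(method)
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    stop_clutchfit("`values` must be a non-empty numeric vector without NAs",
                   "clutchfit_invalid_input")
  }
  n <- length(values)
  m <- mean(values)
  if (method == "normal") {
    if (n == 1L) {
      return(list(mean = m, ci_low = NA_real_, ci_high = NA_real_,
                  n = n, method = method))
    }
    half <- stats::qt(0.975, df = n - 1L) * stats::sd(values) / sqrt(n)
    return(list(mean = m, ci_low = m - half, ci_high = m + half,
                n = n, method = method))
  }
  if (any(values < 0) || any(values != floor(values))) {
    stop_clutchfit("Poisson method requires non-negative integer counts",
                   "clutchfit_invalid_input")
  }
  s <- sum(values)
  low <- if (s == 0) 0 else stats::qchisq(0.025, df = 2 * s) / 2 / n
  high <- stats::qchisq(0.975, df = 2 * (s + 1)) / 2 / n
  list(mean = m, ci_low = low, ci_high = high, n = n, method = method)
}

#' Descriptive group summaries for host-availability experiments
#'
#' Per experimental group (e.g. 12 native hosts / 6 native hosts / 6 native
#' plus 6 non-native hosts): mean clutch size over parasitised native hosts
#' and mean total emerged offspring per female, each with a 95% confidence
#' interval. These are descriptive statistics only — no mixed-model
#' inference is performed here.
#'
#' @param hosts Data frame with columns `mother_id`, `host_type`,
#'   `clutch_size` and a `group` column (or supply `groups`).
#' @param groups Optional data frame `mother_id`, `group` when `hosts`
#'   lacks a group column.
#' @param clutch_method,total_method CI method per measure, `"normal"` or
#'   `"poisson"` (see [summarize_ci()]).
#' @return A data frame: one row per group x measure (`clutch_size`,
#'   `offspring_per_female`) with `n`, `mean`, `ci_low`, `ci_high`,
#'   `method`.
#' @export
exp2_descriptives <- function(hosts, groups = NULL,
                              clutch_method = "normal",
                              total_method = "normal") {
  req <- c("mother_id", "host_type", "clutch_size")
  missing_cols <- setdiff(req, names(hosts))
  if (length(missing_cols)) {
    stop_clutchfit(sprintf("host records: missing column(s) %s",
                           paste(missing_cols, collapse = ", ")),
                   "clutchfit_validation")
  }
  if (!"group" %in% names(hosts)) {
    if (is.null(groups)) {
      stop_clutchfit("supply a `group` column in `hosts` or a `groups` data frame",
                     "clutchfit_validation")
    }
    hosts$group <- groups$group[match(hosts$mother_id, groups$mother_id)]
  }
  if (anyNA(hosts$group)) {
    stop_clutchfit("some mothers have no group label", "clutchfit_validation")
  }
  if (nrow(hosts) == 0L) {
    stop_clutchfit("no host records to summarise", "clutchfit_validation")
  }
  out <- list()
  for (g in unique(hosts$group)) {
    hg <- hosts[hosts$group == g, , drop = FALSE]
    if (nrow(hg) == 0L) {
      stop_clutchfit(sprintf("group '%s' is empty", g), "clutchfit_validation")
    }
    # Clutch size: per parasitised native host (emerged clutches only).
    parasitised <- hg[hg$host_type == "native" & hg$clutch_size > 0, , drop = FALSE]
    if (nrow(parasitised) == 0L) {
      stop_clutchfit(sprintf("group '%s' has no parasitised native hosts", g),
                     "clutchfit_validation")
    }
    clutch <- summarize_ci(parasitised$clutch_size, clutch_method)
    # Offspring per female: emerged offspring summed over her native hosts.
    per_female <- tapply(
      ifelse(hg$host_type == "native", hg$clutch_size, 0),
      hg$mother_id, sum
    )
    totals <- summarize_ci(as.numeric(per_female), total_method)
    out[[length(out) + 1L]] <- data.frame(
      group = g,
      measure = c("clutch_size", "offspring_per_female"),
      n = c(clutch$n, totals$n),
      mean = c(clutch$mean, totals$mean),
      ci_low = c(clutch$ci_low, totals$ci_low),
      ci_high = c(clutch$ci_high, totals$ci_high),
      method = c(clutch$method, totals$method)
    )
  }
  do.call(rbind, out)
}
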