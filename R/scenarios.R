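# Host-environment scenarios and multi-generation projection. Everything
# here is expected-value arithmetic (linearity of expectation over hosts,
# deterministic recursion over generations) — no stochastic simulation.

#' A host environment: native and non-native host counts
#'
#' @param n_native,n_non_native Host counts (`>= 0`). Non-native hosts
#'   accept eggs but yield no emerged offspring.
#' @return An object of class `host_environment`.
#' @export
host_environment <- function(n_native, n_non_native = 0L) {
  structure(
    list(n_native = check_count(n_native, "n_native"),
         n_non_native = check_count(n_non_native, "n_non_native")),
    class = "host_environment"
  )
}

#' Per-host-type clutch frequency distribution
#'
#' A probability mass over clutch outcomes for each host type: rows give
#' the probability that a host of that type receives a clutch of
#' `clutch_size` with `n_females` females (`clutch_size = 0` is the
#' unparasitised outcome). Probabilities must sum to 1 within each host
#' type. Such distributions are typically estimated as empirical clutch
#' frequencies from trial data; they are inputs here, never hard-coded.
#'
#' @param df Data frame with columns `host_type` (`"native"`/`"non_native"`),
#'   `clutch_size`, `n_females`, `prob`.
#' @return An object of class `clutch_distribution` (a validated data frame).
#' @export
#' @examples
#' clutch_distribution(data.frame(
#'   host_type = "native", clutch_size = c(0, 1), n_females = c(0, 1),
#'   prob = c(0.5, 0.5)))
clutch_distribution <- function(df) {
  req <- c("host_type", "clutch_size", "n_females", "prob")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_clutchfit(sprintf("clutch distribution: missing column(s) %s",
                           paste(missing_cols, collapse = ", ")),
                   "clutchfit_validation")
  }
  if (!all(df$host_type %in% c("native", "non_native"))) {
    stop_clutchfit("host_type must be 'native' or 'non_native'", "clutchfit_validation")
  }
  if (any(df$prob < 0) || any(!is.finite(df$prob))) {
    stop_clutchfit("probabilities must be finite and non-negative", "clutchfit_validation")
  }
  if (any(df$clutch_size < 0 | df$clutch_size != floor(df$clutch_size)) ||
      any(df$n_females < 0 | df$n_females > df$clutch_size)) {
    stop_clutchfit("clutch_size must be a non-negative integer and n_females in [0, clutch_size]",
                   "clutchfit_validation")
  }
  for (type in unique(df$host_type)) {
    s <- sum(df$prob[df$host_type == type])
    if (abs(s - 1) > 1e-8) {
      stop_clutchfit(sprintf("probabilities for host type '%s' sum to %.6g, not 1", type, s),
                     "clutchfit_validation")
    }
  }
  structure(as.data.frame(df), class = c("clutch_distribution", "data.frame"))
}

#' Expected F1/F2 fertility of a host environment
#'
#' By linearity of expectation over hosts: expected emerged F1 offspring is
#' the native host count times the expected clutch size on native hosts;
#' expected eggs laid adds the non-native side; expected F2 is the native
#' host count times `E[n_females * f(clutch_size)]`.
#'
#' @param env A [host_environment].
#' @param dist A [clutch_distribution] covering every host type present.
#' @param table A [fertility_table].
#' @return A list of class `scenario_result` with `expected_eggs_laid`,
#'   `expected_f1`, `expected_f2` and a `per_host_type` breakdown (per-host
#'   expected clutch size and F2 by type).
#' @export
expected_scenario <- function(env, dist, table) {
  stopifnot(inherits(env, "host_environment"),
            inherits(dist, "clutch_distribution"),
            inherits(table, "fertility_table"))
  counts <- c(native = env$n_native, non_native = env$n_non_native)
  per_type <- lapply(names(counts)[counts > 0], function(type) {
    rows <- dist[dist$host_type == type, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop_clutchfit(sprintf("no clutch distribution supplied for host type '%s'", type),
                     "clutchfit_validation")
    }
    f2_one <- sum(vapply(seq_len(nrow(rows)), function(i) {
      if (rows$clutch_size[i] == 0) return(0)
      rows$prob[i] * rows$n_females[i] * fertility_of(table, rows$clutch_size[i])
    }, numeric(1)))
    data.frame(host_type = type, n_hosts = counts[[type]],
               e_clutch = sum(rows$prob * rows$clutch_size),
               e_f2_per_host = if (type == "native") f2_one else 0)
  })
  per_type <- do.call(rbind, per_type)
  if (is.null(per_type)) {
    per_type <- data.frame(host_type = character(0), n_hosts = numeric(0),
                           e_clutch = numeric(0), e_f2_per_host = numeric(0))
  }
  native <- per_type[per_type$host_type == "native", , drop = FALSE]
  result <- list(
    expected_eggs_laid = sum(per_type$n_hosts * per_type$e_clutch),
    expected_f1 = if (nrow(native)) native$n_hosts * native$e_clutch else 0,
    expected_f2 = if (nrow(native)) native$n_hosts * native$e_f2_per_host else 0,
    per_host_type = per_type
  )
  class(result) <- "scenario_result"
  result
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> E[eggs laid] = %.4g, E[F1] = %.4g, E[F2] = %.4g\n",
              x$expected_eggs_laid, x$expected_f1, x$expected_f2))
  invisible(x)
}

#' Percent change of a scenario against a baseline
#'
#' `100 * (scenario - baseline) / baseline` for expected F1 and expected
#' F2. Rounding to the nearest percent (half away from zero) is a
#' reporting-layer choice, on by default.
#'
#' @param scenario,baseline [expected_scenario()] results; the baseline
#'   must have strictly positive expected F1 and F2.
#' @param rounded Round to the nearest percent?
#' @return A list with `f1_pct` and `f2_pct`.
#' @export
percent_change <- function(scenario, baseline, rounded = TRUE) {
  stopifnot(inherits(scenario, "scenario_result"),
            inherits(baseline, "scenario_result"))
  if (baseline$expected_f1 <= 0 || baseline$expected_f2 <= 0) {
    stop_clutchfit("percent change undefined: baseline expected F1/F2 must be positive",
                   "clutchfit_invalid_input")
  }
  d <- c(
    f1_pct = 100 * (scenario$expected_f1 - baseline$expected_f1) / baseline$expected_f1,
    f2_pct = 100 * (scenario$expected_f2 - baseline$expected_f2) / baseline$expected_f2
  )
  if (rounded) d <- round_half_away(d)
  as.list(d)
}

#' Fixed-clutch allocation strategy
#'
#' Strategy closure for [project_generations()]: lay clutches of a fixed
#' size in every available host, up to the egg budget. Host shares are
#' expected values and may be fractional.
#'
#' @param size Clutch size to lay everywhere.
#' @return A function `(n_hosts, egg_load, table) -> data.frame(size, n_hosts)`.
#' @export
strategy_fixed_clutch <- function(size = 1L) {
  size <- check_count(size, "size", min = 1L)
  function(n_hosts, egg_load, table) {
    fertility_of(table, size)  # fail early if the table lacks this clutch size
    data.frame(size = size, n_hosts = min(n_hosts, egg_load / size))
  }
}

#' Per-host-optimal allocation strategy
#'
#' Lays in every available host the clutch size maximising the all-female
#' per-host product `k * f(k)` — the F2-optimal choice when hosts, not
#' eggs, limit reproduction.
#'
#' @return A strategy function as in [strategy_fixed_clutch()].
#' @export
strategy_best_per_host <- function() {
  function(n_hosts, egg_load, table) {
    k <- seq_len(table$max_clutch)
    product <- k * unname(table$f)
    best <- k[which.max(product)]
    data.frame(size = best, n_hosts = min(n_hosts, egg_load / best))
  }
}

#' Project parasitoid population density over generations
#'
#' Deterministic expected-value recursion: each generation's total host
#' supply is divided equally among its adult females (fractional shares
#' allowed); each female allocates clutches over her share using the
#' strategy, limited by her egg load; the next generation's adults are the
#' expected offspring emerging from native hosts, split by the sex ratio.
#' Fractional individuals are carried exactly — this is a density
#' projection, not an individual-based simulation.
#'
#' @param table A [fertility_table].
#' @param strategy A strategy function (see [strategy_fixed_clutch()]):
#'   called with the per-female host share, egg load and table, returning a
#'   data frame of `size` and (possibly fractional) `n_hosts`.
#' @param hosts_per_generation Numeric vector of total hosts available in
#'   each generation, recycled to `n_generations`.
#' @param founders Founding adult females (generation 0).
#' @param sex_ratio Female fraction among offspring (default 0.75, the 3:1
#'   female-biased ratio of gregarious parasitoids).
#' @param egg_load Eggs per female (default `Inf`: proovigenic egg limits
#'   exist but are species-specific; supply a number to impose one).
#' @param n_generations Generations to project (`>= 1`).
#' @return A data frame of class `projection_trace`: one row per generation
#'   `0..n_generations` with `generation`, `n_females`, `n_males`,
#'   `hosts_available` and `f2_capacity` (total egg complement of that
#'   generation's females; `NA` for the founders, whose rearing clutch size
#'   is outside the projection). Attribute `generation_time_days` records
#'   the species' 12-14 day generation time as metadata.
#' @export
#' @examples
#' project_generations(default_fertility_table(), strategy_fixed_clutch(1),
#'                     hosts_per_generation = 12, founders = 1,
#'                     n_generations = 1)
project_generations <- function(table, strategy, hosts_per_generation,
                                founders, sex_ratio = 0.75, egg_load = Inf,
                                n_generations = 1L) {
  stopifnot(inherits(table, "fertility_table"), is.function(strategy))
  n_generations <- check_count(n_generations, "n_generations", min = 1L)
  if (!is.numeric(founders) || length(founders) != 1L || founders < 0) {
    stop_clutchfit("`founders` must be a single non-negative number",
                   "clutchfit_invalid_input")
  }
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1) {
    stop_clutchfit("`sex_ratio` must be a female fraction in [0, 1]",
                   "clutchfit_invalid_input")
  }
  if (!is.numeric(hosts_per_generation) || any(hosts_per_generation < 0)) {
    stop_clutchfit("`hosts_per_generation` must be non-negative",
                   "clutchfit_invalid_input")
  }
  hosts <- rep_len(as.numeric(hosts_per_generation), n_generations)

  females <- numeric(n_generations + 1L)
  males <- numeric(n_generations + 1L)
  f2_capacity <- rep(NA_real_, n_generations + 1L)
  females[1L] <- founders

  for (g in seq_len(n_generations)) {
    prev <- females[g]
    if (prev <= 0 || hosts[g] <= 0) {
      females[g + 1L] <- 0
      males[g + 1L] <- 0
      f2_capacity[g + 1L] <- 0
      next
    }
    share <- hosts[g] / prev
    plan <- strategy(share, egg_load, table)
    if (!is.data.frame(plan) || !all(c("size", "n_hosts") %in% names(plan)) ||
        any(plan$n_hosts < 0)) {
      stop_clutchfit("strategy must return a data frame with columns size and n_hosts >= 0",
                     "clutchfit_strategy")
    }
    if (sum(plan$n_hosts) > share + 1e-9) {
      stop_clutchfit("strategy allocated more hosts than the per-female share",
                     "clutchfit_strategy")
    }
    if (sum(plan$size * plan$n_hosts) > egg_load + 1e-9) {
      stop_clutchfit("strategy exceeded the egg load", "clutchfit_strategy")
    }
    offspring_per_female <- sum(plan$size * plan$n_hosts)
    f2_per_female <- sum(vapply(seq_len(nrow(plan)), function(i) {
      plan$n_hosts[i] * plan$size[i] * sex_ratio * fertility_of(table, plan$size[i])
    }, numeric(1)))
    females[g + 1L] <- prev * offspring_per_female * sex_ratio
    males[g + 1L] <- prev * offspring_per_female * (1 - sex_ratio)
    f2_capacity[g + 1L] <- prev * f2_per_female
  }

  trace <- data.frame(
    generation = 0:n_generations,
    n_females = females,
    n_males = males,
    hosts_available = c(NA_real_, hosts),
    f2_capacity = f2_capacity
  )
  attr(trace, "generation_time_days") <- c(12, 14)
  class(trace) <- c("projection_trace", "data.frame")
  trace
}
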