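# Combinatorial enumeration of clutch compositions and host allocations,
# plus exhaustive searches over the allocation space. At the scales a
# female actually faces (a dozen hosts, a few dozen eggs) exhaustive
# enumeration is exact and fast; the search-space caps below make the
# boundary explicit rather than letting enumeration blow up silently.

MAX_SEARCH_HOSTS <- 20L
MAX_SEARCH_OFFSPRING <- 40L

#' Enumerate all clutch compositions up to a maximum clutch size
#'
#' Every (clutch size, number of females) pair a female can choose when she
#' discovers a host egg: for each size `k` in `1..max_clutch` there are
#' `k + 1` sex splits, giving `max_clutch * (max_clutch + 3) / 2` options in
#' total — 35 when clutches of up to 7 are possible.
#'
#' @param max_clutch Maximum clutch size, `1..7`.
#' @return A data frame with columns `size`, `n_females`, `n_males`.
#' @export
#' @examples
#' nrow(enumerate_compositions(7))  # 35
enumerate_compositions <- function(max_clutch) {
  max_clutch <- check_count(max_clutch, "max_clutch", min = 1L)
  if (max_clutch > MAX_CLUTCH_ABS) {
    stop_clutchfit(sprintf("`max_clutch` must be in 1..%d", MAX_CLUTCH_ABS),
                   "clutchfit_invalid_input")
  }
  size <- rep.int(seq_len(max_clutch), seq_len(max_clutch) + 1L)
  n_females <- unlist(lapply(seq_len(max_clutch), function(k) 0:k))
  data.frame(size = size, n_females = n_females, n_males = size - n_females)
}

#' Enumerate clutch-size allocations of offspring over hosts
#'
#' All distinct ways to distribute `n_offspring` offspring over at most
#' `n_hosts` identical hosts with clutch sizes in `1..max_clutch`: the
#' bounded integer partitions of `n_offspring` into at most `n_hosts` parts
#' each at most `max_clutch`. Host identity carries no information, so an
#' allocation is a multiset, returned in canonical non-increasing form, the
#' list ordered lexicographically non-increasingly.
#'
#' @param n_hosts Available hosts (`0..20`).
#' @param n_offspring Offspring to place (`0..40`).
#' @param max_clutch Maximum clutch size per host.
#' @return A list of integer vectors (each non-increasing); `n_offspring = 0`
#'   yields the single empty allocation, infeasible inputs an empty list.
#' @export
#' @examples
#' enumerate_size_allocations(3, 4, max_clutch = 4)
enumerate_size_allocations <- function(n_hosts, n_offspring, max_clutch = 4L) {
  n_hosts <- check_count(n_hosts, "n_hosts")
  n_offspring <- check_count(n_offspring, "n_offspring")
  max_clutch <- check_count(max_clutch, "max_clutch", min = 1L)
  if (n_hosts > MAX_SEARCH_HOSTS || n_offspring > MAX_SEARCH_OFFSPRING) {
    stop_clutchfit(
      sprintf("search space capped at %d hosts and %d offspring (exhaustive enumeration only)",
              MAX_SEARCH_HOSTS, MAX_SEARCH_OFFSPRING),
      "clutchfit_search_cap"
    )
  }
  bounded_partitions(n_offspring, min(max_clutch, n_offspring), n_hosts)
}

# Partitions of n into at most max_parts parts, each <= max_part, generated
# with parts non-increasing, in lexicographically non-increasing order.
bounded_partitions <- function(n, max_part, max_parts) {
  if (n == 0L) return(list(integer(0)))
  if (max_parts <= 0L || max_part <= 0L) return(list())
  out <- list()
  for (k in seq.int(min(n, max_part), 1L)) {
    for (tail in bounded_partitions(n - k, k, max_parts - 1L)) {
      out[[length(out) + 1L]] <- c(k, tail)
    }
  }
  out
}

# All-female F2 of a clutch-size multiset: sum of k * f(k).
sizes_f2 <- function(table, sizes) {
  if (length(sizes) == 0L) return(0)
  sum(vapply(sizes, function(k) k * fertility_of(table, k), numeric(1)))
}

#' Find the F2-maximising allocations of offspring over hosts
#'
#' Exhaustively scores every allocation from [enumerate_size_allocations()]
#' under the all-female accounting (per-host F2 = `k * f(k)`) and returns
#' all allocations attaining the maximum — ties are genuine alternative
#' optima, not broken arbitrarily.
#'
#' @param table A [fertility_table].
#' @param n_hosts Available hosts.
#' @param n_offspring Offspring that must all be placed.
#' @return A list with `allocations` (list of size multisets, canonical
#'   order) and `f2` (the maximal F2).
#' @export
#' @examples
#' optimal_allocation(default_fertility_table(), n_hosts = 2, n_offspring = 6)
optimal_allocation <- function(table, n_hosts, n_offspring) {
  allocs <- enumerate_size_allocations(n_hosts, n_offspring, table$max_clutch)
  if (length(allocs) == 0L) {
    stop_clutchfit(
      sprintf("infeasible: cannot place %d offspring in %d hosts with clutches up to %d",
              n_offspring, n_hosts, table$max_clutch),
      "clutchfit_infeasible"
    )
  }
  f2 <- vapply(allocs, sizes_f2, numeric(1), table = table)
  best <- max(f2)
  keep <- f2 >= best - 1e-9
  list(allocations = allocs[keep], f2 = best)
}

strategy_comparison <- function(alloc_a, alloc_b, f1_a, f1_b, f2_a, f2_b, n_hosts) {
  structure(
    list(alloc_a = alloc_a, alloc_b = alloc_b,
         f1_a = f1_a, f1_b = f1_b, f2_a = f2_a, f2_b = f2_b,
         n_hosts = n_hosts),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = "+") else "(none)"
  cat(sprintf("<strategy_comparison> over %d available hosts\n", x$n_hosts))
  cat(sprintf("  A: clutches %s  F1 = %d, F2 = %.4g\n", fmt(x$alloc_a), x$f1_a, x$f2_a))
  cat(sprintf("  B: clutches %s  F1 = %d, F2 = %.4g\n", fmt(x$alloc_b), x$f1_b, x$f2_b))
  invisible(x)
}

#' Witness that equal F1 fertility can yield different F2 fertility
#'
#' Among all allocations of exactly `n_offspring` offspring over `n_hosts`
#' native hosts (so F1 — emerged offspring — is identical), returns the
#' allocation pair with the largest F2 spread, or `NULL` when every
#' allocation gives the same F2 (or only one allocation exists).
#'
#' @inheritParams optimal_allocation
#' @return A `strategy_comparison` (A = highest F2, B = lowest) or `NULL`.
#' @export
#' @examples
#' find_same_f1_different_f2(default_fertility_table(), 2, 6)
find_same_f1_different_f2 <- function(table, n_hosts, n_offspring) {
  allocs <- enumerate_size_allocations(n_hosts, n_offspring, table$max_clutch)
  if (length(allocs) < 2L) return(NULL)
  f2 <- vapply(allocs, sizes_f2, numeric(1), table = table)
  hi <- which.max(f2)
  lo <- which.min(f2)
  if (f2[hi] - f2[lo] <= 1e-9) return(NULL)
  strategy_comparison(allocs[[hi]], allocs[[lo]],
                      f1_a = n_offspring, f1_b = n_offspring,
                      f2_a = f2[hi], f2_b = f2[lo], n_hosts = n_hosts)
}

#' Witness that lower F1 fertility can yield higher F2 fertility
#'
#' Searches exhaustively over every offspring total and every allocation on
#' the same set of available hosts (hosts may remain unparasitised) for a
#' pair A, B with strictly fewer emerged F1 offspring in A yet strictly
#' higher F2. Among all witnesses the pair maximising the F2 advantage of A
#' is returned (ties broken towards smaller F1 counts).
#'
#' @param table A [fertility_table].
#' @param n_hosts Available hosts (`<= 20`).
#' @return A `strategy_comparison` with `f1_a < f1_b` and `f2_a > f2_b`, or
#'   `NULL` if no such pair exists.
#' @export
#' @examples
#' find_lower_f1_higher_f2(default_fertility_table(), 6)
find_lower_f1_higher_f2 <- function(table, n_hosts) {
  n_hosts <- check_count(n_hosts, "n_hosts")
  if (n_hosts > MAX_SEARCH_HOSTS) {
    stop_clutchfit(sprintf("search space capped at %d hosts", MAX_SEARCH_HOSTS),
                   "clutchfit_search_cap")
  }
  n_max <- min(n_hosts * table$max_clutch, MAX_SEARCH_OFFSPRING)
  # For each offspring total, the best- and worst-F2 allocations suffice:
  # a witness pair exists iff max-F2 at some lower total beats min-F2 at
  # some higher total.
  per_n <- lapply(0:n_max, function(n) {
    allocs <- enumerate_size_allocations(n_hosts, n, table$max_clutch)
    if (length(allocs) == 0L) return(NULL)
    f2 <- vapply(allocs, sizes_f2, numeric(1), table = table)
    list(n = n, best = allocs[[which.max(f2)]], best_f2 = max(f2),
         worst = allocs[[which.min(f2)]], worst_f2 = min(f2))
  })
  per_n <- Filter(Negate(is.null), per_n)
  winner <- NULL
  for (a in per_n) {
    for (b in per_n) {
      if (a$n >= b$n) next
      gap <- a$best_f2 - b$worst_f2
      if (gap > 1e-9 && (is.null(winner) || gap > winner$gap + 1e-9)) {
        winner <- list(a = a, b = b, gap = gap)
      }
    }
  }
  if (is.null(winner)) return(NULL)
  strategy_comparison(winner$a$best, winner$b$worst,
                      f1_a = winner$a$n, f1_b = winner$b$n,
                      f2_a = winner$a$best_f2, f2_b = winner$b$worst_f2,
                      n_hosts = n_hosts)
}

#' Compare solitary and gregarious host use on the same host supply
#'
#' Expected-value comparison of the two life-history strategies. The
#' solitary strategy places a single offspring in each host; the gregarious
#' strategy places the supplied clutch-size multiset. Expected females per
#' clutch are `size * female fraction` (fractional females allowed), the
#' conventional sex ratios being 1:1 (fraction 0.5) for solitary and a
#' female-biased 3:1 (fraction 0.75) for gregarious parasitoids.
#'
#' @param table A [fertility_table].
#' @param n_hosts Available hosts (all used by the solitary strategy).
#' @param gregarious_sizes Clutch-size multiset laid by the gregarious
#'   female; must fit within `n_hosts`.
#' @param solitary_sex_ratio,gregarious_sex_ratio Female fractions in
#'   `[0, 1]`.
#' @return A list with `f2_solitary` and `f2_gregarious` (expected eggs).
#' @export
#' @examples
#' compare_solitary_gregarious(default_fertility_table(), 12, rep(1, 12))
compare_solitary_gregarious <- function(table, n_hosts, gregarious_sizes,
                                        solitary_sex_ratio = 0.5,
                                        gregarious_sex_ratio = 0.75) {
  n_hosts <- check_count(n_hosts, "n_hosts")
  for (r in c(solitary_sex_ratio, gregarious_sex_ratio)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1) {
      stop_clutchfit("sex ratios must be female fractions in [0, 1]",
                     "clutchfit_invalid_input")
    }
  }
  if (length(gregarious_sizes) > n_hosts) {
    stop_clutchfit("gregarious clutch sizes exceed the available hosts",
                   "clutchfit_invalid_input")
  }
  f2_greg <- if (length(gregarious_sizes) == 0L) 0 else {
    sum(vapply(gregarious_sizes, function(k)
      k * gregarious_sex_ratio * fertility_of(table, k), numeric(1)))
  }
  list(
    f2_solitary = n_hosts * solitary_sex_ratio * fertility_of(table, 1L),
    f2_gregarious = f2_greg
  )
}

#' Tabulate an allocation search space for export
#'
#' One row per enumerated allocation with its emerged-F1 count, eggs laid
#' and all-female F2 — the flat form written by the `optimize` pipeline
#' stage for downstream inspection.
#'
#' @inheritParams optimal_allocation
#' @return A data frame with columns `sizes` (e.g. `"4+2"`), `f1`,
#'   `eggs_laid`, `f2`.
#' @export
allocation_table <- function(table, n_hosts, n_offspring) {
  allocs <- enumerate_size_allocations(n_hosts, n_offspring, table$max_clutch)
  data.frame(
    sizes = vapply(allocs, function(s)
      if (length(s)) paste(s, collapse = "+") else "", character(1)),
    f1 = vapply(allocs, sum, numeric(1)),
    eggs_laid = vapply(allocs, sum, numeric(1)),
    f2 = vapply(allocs, sizes_f2, numeric(1), table = table)
  )
}
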