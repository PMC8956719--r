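point_dist <- function(size, n_females, host_type = "native") {
  clutch_distribution(data.frame(
    host_type = host_type, clutch_size = size, n_females = n_females, prob = 1))
}

both_types_dist <- function(size, n_females) {
  clutch_distribution(data.frame(
    host_type = c("native", "non_native"),
    clutch_size = size, n_females = n_females, prob = 1))
}

test_that("expected scenario applies linearity of expectation over hosts", {
  res <- expected_scenario(host_environment(6, 0), point_dist(2, 2), tbl)
  expect_equal(res$expected_f1, 12)
  expect_equal(res$expected_f2, 165.6)
  expect_equal(res$expected_eggs_laid, 12)

  none <- expected_scenario(host_environment(0, 6), both_types_dist(2, 2), tbl)
  expect_equal(none$expected_f1, 0)
  expect_equal(none$expected_f2, 0)
  expect_equal(none$expected_eggs_laid, 12)  # eggs still spent

  half <- clutch_distribution(data.frame(
    host_type = "native", clutch_size = c(0, 1), n_females = c(0, 1),
    prob = c(0.5, 0.5)))
  one <- expected_scenario(host_environment(1, 0), half, tbl)
  expect_equal(one$expected_f1, 0.5)
  expect_equal(one$expected_f2, 9.65)
})

test_that("expected scenario scales linearly in host counts", {
  dist <- clutch_distribution(data.frame(
    host_type = c("native", "native", "non_native"),
    clutch_size = c(1, 3, 2), n_females = c(1, 2, 1),
    prob = c(0.4, 0.6, 1)))
  base <- expected_scenario(host_environment(5, 3), dist, tbl)
  doubled <- expected_scenario(host_environment(10, 6), dist, tbl)
  expect_equal(doubled$expected_f1, 2 * base$expected_f1)
  expect_equal(doubled$expected_f2, 2 * base$expected_f2)
  expect_equal(doubled$expected_eggs_laid, 2 * base$expected_eggs_laid)
  expect_lte(base$expected_f1, base$expected_eggs_laid)
})

test_that("removing non-native hosts never lowers expected F1 or F2", {
  dist <- both_types_dist(2, 1)
  with_nn <- expected_scenario(host_environment(6, 6), dist, tbl)
  without <- expected_scenario(host_environment(6, 0), dist, tbl)
  expect_gte(without$expected_f1, with_nn$expected_f1)
  expect_gte(without$expected_f2, with_nn$expected_f2)
  expect_lte(without$expected_eggs_laid, with_nn$expected_eggs_laid)
})

test_that("scenario distributions are validated", {
  expect_error(clutch_distribution(data.frame(
    host_type = "native", clutch_size = 1, n_females = 1, prob = 0.7)),
    class = "clutchfit_validation")
  expect_error(clutch_distribution(data.frame(
    host_type = "native", clutch_size = 2, n_females = 3, prob = 1)),
    class = "clutchfit_validation")
  expect_error(clutch_distribution(data.frame(
    host_type = "elsewhere", clutch_size = 1, n_females = 1, prob = 1)),
    class = "clutchfit_validation")
  # Distribution must cover every host type present in the environment.
  expect_error(
    expected_scenario(host_environment(1, 1), point_dist(1, 1), tbl),
    class = "clutchfit_validation")
  # Clutch sizes beyond the table cannot be scored.
  expect_error(
    expected_scenario(host_environment(1, 0), point_dist(5, 5), tbl),
    class = "clutchfit_missing_fertility")
})

test_that("percent change compares scenarios against a baseline", {
  baseline <- expected_scenario(host_environment(12, 0), point_dist(2, 2), tbl)
  same <- percent_change(baseline, baseline)
  expect_equal(same$f1_pct, 0)
  expect_equal(same$f2_pct, 0)

  mixed <- expected_scenario(host_environment(6, 6), both_types_dist(1, 1), tbl)
  delta <- percent_change(mixed, baseline)
  expect_equal(delta$f1_pct, -75)   # F1: 24 -> 6
  expect_equal(delta$f2_pct, -65)   # F2: 331.2 -> 115.8, -65.04 rounded

  exact <- percent_change(mixed, baseline, rounded = FALSE)
  expect_equal(exact$f2_pct, 100 * (115.8 - 331.2) / 331.2)

  # Invariant under common rescaling of both scenarios.
  b2 <- expected_scenario(host_environment(24, 0), point_dist(2, 2), tbl)
  m2 <- expected_scenario(host_environment(12, 12), both_types_dist(1, 1), tbl)
  expect_equal(percent_change(m2, b2), delta)

  empty <- expected_scenario(host_environment(0, 0), point_dist(1, 1), tbl)
  expect_error(percent_change(mixed, empty), class = "clutchfit_invalid_input")
})

test_that("projection recursion reproduces closed-form expectations", {
  extinct <- project_generations(tbl, strategy_fixed_clutch(1),
                                 hosts_per_generation = 0, founders = 5,
                                 n_generations = 3)
  expect_equal(extinct$n_females[-1], rep(0, 3))

  one <- project_generations(tbl, strategy_fixed_clutch(1),
                             hosts_per_generation = 12, founders = 1,
                             n_generations = 1)
  expect_equal(one$n_females[2], 9)   # 12 hosts x 0.75 female fraction

  two <- project_generations(tbl, strategy_fixed_clutch(1),
                             hosts_per_generation = c(12, 108), founders = 1,
                             n_generations = 2)
  expect_equal(two$n_females[3], 81)  # 9 females x 12 hosts each x 0.75
  expect_equal(two$n_males[3], 27)
  expect_equal(two$f2_capacity[2], 12 * 0.75 * 19.3)
  expect_equal(attr(two, "generation_time_days"), c(12, 14))
})

test_that("projection respects egg load and grows under the optimal strategy", {
  limited <- project_generations(tbl, strategy_fixed_clutch(1),
                                 hosts_per_generation = 12, founders = 1,
                                 egg_load = 5, n_generations = 1)
  expect_equal(limited$n_females[2], 5 * 0.75)

  # k * f(k) increasing and hosts unlimited: the per-host-optimal strategy
  # never shrinks the population once it can grow.
  growth <- project_generations(tbl, strategy_best_per_host(),
                                hosts_per_generation = c(10, 100, 1000, 10000),
                                founders = 2, n_generations = 4)
  expect_true(all(diff(growth$n_females) >= 0))

  bad_strategy <- function(n_hosts, egg_load, table) {
    data.frame(size = 1, n_hosts = n_hosts + 5)
  }
  expect_error(project_generations(tbl, bad_strategy, 12, 1),
               class = "clutchfit_strategy")
})
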