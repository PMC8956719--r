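test_that("the regression recovers collinear data exactly and rejects degenerate designs", {
  wing <- c(0.31, 0.47, 0.52, 0.66, 0.8)
  mothers <- data.frame(wing_length_mm = wing, fertility = 2 + 30 * wing)
  line <- suppressWarnings(fit_wing_fertility(mothers))  # perfect-fit notice
  expect_lt(abs(line$intercept - 2) / 2, 1e-8)
  expect_lt(abs(line$slope - 30) / 30, 1e-8)
  expect_equal(line$r_squared, 1)

  expect_error(fit_wing_fertility(mothers[1:2, ]), class = "clutchfit_validation")
  expect_error(fit_wing_fertility(
    data.frame(wing_length_mm = rep(0.5, 4), fertility = 1:4)),
    class = "clutchfit_singular_fit")
  expect_error(fit_wing_fertility(data.frame(wing_length_mm = 1:3)),
               class = "clutchfit_validation")
})

test_that("the regression recovers the generating slope from synthetic mothers", {
  cfg <- default_generator_config()
  trial <- generate_trial(cfg, seed = 7)
  line <- fit_wing_fertility(trial$mothers)
  expect_lt(abs(line$slope - cfg$fertility_model$beta), 3 * line$se[2])
})

test_that("fertility tables built from offspring average female predictions", {
  line <- regression_line(2, 30)
  # Constant wing length per clutch size: f(k) is exactly the prediction.
  off <- data.frame(
    offspring_id = sprintf("O%02d", 1:6),
    host_id = rep(c("h1", "h2", "h3"), times = c(1, 2, 3)),
    clutch_size = rep(c(1, 2, 3), times = c(1, 2, 3)),
    sex = c("F", "F", "M", "F", "F", "F"),
    wing_length_mm = rep(c(0.5, 0.4, 0.3), times = c(1, 2, 3))
  )
  recovered <- build_fertility_table(off, line, max_clutch = 3)
  expect_equal(unname(recovered$f), 2 + 30 * c(0.5, 0.4, 0.3))
  # h2 has 1 female of 2; h3 has 3 females of 3.
  expect_equal(unname(recovered$mean_females_per_host), c(1, 1, 3))

  # A single host of clutch 2 with 1F + 1M: mean females per host is 1.
  pair <- off[off$host_id == "h2", ]
  tab2 <- build_fertility_table(pair, line, max_clutch = 2)
  expect_equal(tab2$mean_females_per_host[["2"]], 1)
  expect_false(tab2$complete)  # clutch 1 unobserved -> flagged incomplete

  # All-male clutches leave f(k) undefined, and scoring them errors.
  males <- data.frame(offspring_id = "O1", host_id = "h9", clutch_size = 1,
                      sex = "M", wing_length_mm = 0.5)
  tabm <- build_fertility_table(males, line, max_clutch = 1)
  expect_false(tabm$complete)
  expect_error(per_host_f2(tabm, clutch_composition(1, 1)),
               class = "clutchfit_missing_fertility")

  bad <- off
  bad$clutch_size[2] <- 4  # disagrees with the host's offspring count
  expect_error(build_fertility_table(bad, line), class = "clutchfit_validation")
})

test_that("estimation recovers generating fertilities and closes the loop to F2", {
  cfg <- generator_config(n_mothers = 300)
  trial <- generate_trial(cfg, seed = 11)
  line <- fit_wing_fertility(trial$mothers)
  emerged <- trial$offspring[trial$offspring$emerges, ]
  recovered <- build_fertility_table(emerged, line, max_clutch = 4)
  truth <- trial$truth$generating_fertility_means
  expect_true(all(abs(recovered$f - truth) / truth < 0.05))
  expect_true(all(abs(recovered$mean_females_per_host -
                        trial$truth$expected_females_per_host) < 0.15))
  # Round trip into the fitness arithmetic: cohort F2 from the recovered
  # table tracks the truth table within the same relative tolerance.
  for (k in 1:4) {
    truth_f2 <- 12 * truth[[k]]
    expect_lt(abs(cohort_f2(recovered, k, 12) - truth_f2) / truth_f2, 0.05)
  }
})

test_that("normal and Poisson confidence intervals follow their closed forms", {
  flat <- summarize_ci(c(5, 5, 5, 5))
  expect_equal(c(flat$mean, flat$ci_low, flat$ci_high), c(5, 5, 5))

  ci <- summarize_ci(c(1, 2, 3, 4, 5))
  expect_equal(ci$mean, 3)
  expect_equal(ci$ci_high - ci$mean, 1.963243, tolerance = 1e-6)
  expect_equal(ci$mean - ci$ci_low, ci$ci_high - ci$mean)

  zero <- summarize_ci(0, method = "poisson")
  expect_equal(zero$ci_low, 0)
  expect_gt(zero$ci_high, 0)

  # Exact Poisson interval agrees with the classical test's interval for
  # the total count, rescaled to the mean.
  for (counts in list(c(0, 1, 3), c(7, 2, 5, 4), 11)) {
    ours <- summarize_ci(counts, method = "poisson")
    ref <- stats::poisson.test(sum(counts))$conf.int / length(counts)
    expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref), tolerance = 1e-10)
  }

  expect_error(summarize_ci(c(1.5, 2), method = "poisson"),
               class = "clutchfit_invalid_input")
  expect_error(summarize_ci(c(-1, 2), method = "poisson"),
               class = "clutchfit_invalid_input")
  single <- summarize_ci(4)
  expect_true(is.na(single$ci_low))
})

test_that("normal intervals achieve nominal coverage", {
  set.seed(402)
  hits <- 0L
  for (i in 1:1000) {
    ci <- summarize_ci(rnorm(20, mean = 10, sd = 3))
    if (ci$ci_low <= 10 && 10 <= ci$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.93)
  expect_lte(hits / 1000, 0.97)
})

test_that("group descriptives summarise clutch size and offspring per female", {
  hosts <- data.frame(
    mother_id = rep(c("m1", "m2", "m3", "m4"), each = 3),
    host_type = "native",
    clutch_size = c(2, 2, 0, 2, 2, 0, 1, 3, 4, 1, 1, 1),
    group = rep(c("a", "a", "b", "b"), each = 3)
  )
  out <- exp2_descriptives(hosts)
  a_clutch <- out[out$group == "a" & out$measure == "clutch_size", ]
  expect_equal(a_clutch$mean, 2)
  expect_equal(a_clutch$ci_low, 2)  # identical clutches: zero-width CI
  a_total <- out[out$group == "a" & out$measure == "offspring_per_female", ]
  expect_equal(a_total$mean, 4)

  # Single female: clutch mean over her parasitised hosts.
  solo <- exp2_descriptives(hosts[hosts$mother_id == "m3", , drop = FALSE])
  expect_equal(solo[solo$measure == "clutch_size", "mean"], mean(c(1, 3, 4)))

  # Generator-built groups: mixed-host females built with smaller clutches
  # than the native-only group order their group means accordingly.
  small <- generator_config(
    n_mothers = 40, hosts_per_mother = 6,
    clutch_behavior = list(native = c(0.2, 0.5, 0.2, 0.1, 0),
                           non_native = c(0.2, 0.5, 0.2, 0.1, 0)))
  big <- generator_config(
    n_mothers = 40, hosts_per_mother = 6,
    clutch_behavior = list(native = c(0.1, 0.1, 0.2, 0.3, 0.3),
                           non_native = c(0.1, 0.1, 0.2, 0.3, 0.3)))
  t_small <- generate_trial(small, seed = 5)$hosts
  t_big <- generate_trial(big, seed = 6)$hosts
  t_small$group <- "mixed_style"
  t_big$group <- "native_style"
  t_big$mother_id <- paste0("B", t_big$mother_id)
  both <- exp2_descriptives(rbind(t_small, t_big))
  m <- both[both$measure == "clutch_size", ]
  expect_lt(m$mean[m$group == "mixed_style"], m$mean[m$group == "native_style"])

  expect_error(exp2_descriptives(hosts[0, , drop = FALSE]),
               class = "clutchfit_validation")
})
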