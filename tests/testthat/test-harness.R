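test_that("scenario specs validate their fields and default sizes", {
  weak <- scenario_spec("independent_normal", "weak")
  expect_equal(weak$n_initial, 10000L)
  expect_equal(weak$control_copies, 0L)
  strong <- scenario_spec("independent_normal", "strong")
  expect_equal(strong$n_initial, 1000L)
  expect_equal(strong$control_copies, 10L)
  expect_error(scenario_spec("independent_normal", "weak", control_copies = 5))
  expect_error(scenario_spec("independent_normal", "weak", target_rd = 0.1))
})

test_that("the canonical grid has 100 uniquely indexed cells, 20 of them null", {
  grid <- scenario_grid()
  expect_length(grid, 100)
  idx <- vapply(grid, scenario_index, integer(1))
  expect_equal(sort(idx), 1:100)
  expect_length(null_grid(), 20)
  expect_true(all(vapply(null_grid(), function(s) s$target_rd, numeric(1)) == 0))
})

test_that("Monte Carlo significance bounds reproduce the decision bands", {
  b <- mc_significance_bounds(0.05, 1825)
  expect_equal(round(c(b$lower, b$upper), 3), c(0.040, 0.060))
  b2 <- mc_significance_bounds(0.95, 1825)
  expect_equal(round(c(b2$lower, b2$upper), 3), c(0.940, 0.960))
  b3 <- mc_significance_bounds(0.5, 100)
  expect_equal(c(b3$lower, b3$upper), c(0.402, 0.598))
})

cs_bern <- calibrate_scenario("independent_bernoulli", "weak", 0.29,
  target_rd = 0, m = 2e5, seed = 51
)
spec_small <- scenario_spec("independent_bernoulli", "weak", 0.29, 0,
  n_initial = 2000L, n_replicates = 40L
)

test_that("replicates are deterministic given spec, coefficients and seed", {
  r1 <- run_replicate(spec_small, cs_bern, seed = 99)
  r2 <- run_replicate(spec_small, cs_bern, seed = 99)
  expect_identical(r1, r2)
  expect_true(r1$valid)
  expect_true(is.finite(r1$rd))
  expect_true(all(is.finite(c(r1$p_pearson, r1$p_mcnemar))))
  r3 <- run_replicate(spec_small, cs_bern, seed = 100)
  expect_false(identical(r1$rd, r3$rd))
})

test_that("scenario metrics aggregate replicates sensibly and deterministically", {
  m1 <- run_scenario(spec_small, cs_bern, master_seed = 5, keep_records = TRUE)
  m2 <- run_scenario(spec_small, cs_bern, master_seed = 5)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_equal(m1$n_replicates_used, 40)
  props <- c(
    m1$type1_pearson, m1$type1_mcnemar,
    m1$coverage_independent, m1$coverage_paired
  )
  expect_true(all(props >= 0 & props <= 1))
  expect_gt(m1$width_ratio, 0)
  expect_gt(m1$mean_matched_pct, 90) # Bernoulli covariates match easily
  # coverage recomputable from the records
  expect_equal(
    m1$coverage_paired,
    mean(m1$records$ci_par_lower <= 0 & m1$records$ci_par_upper >= 0)
  )
})

test_that("an empty matched sample marks the replicate invalid", {
  spec <- scenario_spec("independent_normal", "weak", 0.29, 0,
    n_initial = 500L, n_replicates = 5L
  )
  cs <- calibrate_scenario("independent_normal", "weak", 0.29,
    target_rd = 0, m = 5e4, seed = 52
  )
  rec <- suppressWarnings(
    run_replicate(spec, cs, seed = 7, caliper_multiplier = 0)
  )
  # a zero caliper with continuous propensity scores leaves nothing matchable
  expect_false(rec$valid)
  expect_true(is.na(rec$rd))
  # and a scenario made of such replicates fails as a whole
  expect_error(
    suppressWarnings(
      run_scenario(spec, cs, master_seed = 1, caliper_multiplier = 0)
    ),
    "invalid"
  )
})

test_that("grid calibration shares intercepts within a combination and varies beta", {
  specs <- list(
    scenario_spec("independent_bernoulli", "weak", 0.29, 0),
    scenario_spec("independent_bernoulli", "weak", 0.29, -0.05),
    scenario_spec("independent_bernoulli", "weak", 0.15, 0)
  )
  tab <- calibrate_grid(specs, m = 2e5, seed = 53)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$alpha0_treat[1], tab$alpha0_treat[2])
  expect_equal(tab$alpha0_outcome[1], tab$alpha0_outcome[2])
  expect_lt(tab$beta[2], 0)
  expect_equal(tab$beta[c(1, 3)], c(0, 0))
  expect_lt(tab$alpha0_outcome[3], tab$alpha0_outcome[1])
  # matches the single-cell calibration path on the same sample
  single <- calibrate_scenario("independent_bernoulli", "weak", 0.29,
    target_rd = -0.05, m = 2e5, seed = 53
  )
  expect_equal(tab$beta[2], single$beta, tolerance = 1e-6)
})

test_that("run_grid returns one metrics row per scenario and is reproducible", {
  specs <- list(
    scenario_spec("independent_bernoulli", "weak", 0.29, 0,
      n_initial = 1500L, n_replicates = 25L
    ),
    scenario_spec("independent_bernoulli", "weak", 0.29, -0.05,
      n_initial = 1500L, n_replicates = 25L
    )
  )
  res <- run_grid(specs, master_seed = 2, m = 1e5)
  res2 <- run_grid(specs,
    coeffs_table = attr(res, "coefficients"),
    master_seed = 2
  )
  expect_equal(nrow(res), 2)
  expect_equal(res$type1_mcnemar[2], NA_real_) # non-null cell
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("grid summaries follow the interpolated quantile rule", {
  fake <- data.frame(
    covariate_scenario = "independent_normal",
    selection_strength = "weak",
    baseline_outcome_prob = 0.29,
    target_rd = c(-0.02, -0.05, -0.1),
    scenario_index = 2:4,
    mean_matched_pct = 90,
    type1_pearson = NA_real_, type1_mcnemar = NA_real_,
    coverage_independent = c(1, 2, 3), # synthetic values for the quantile rule
    coverage_paired = 0.95,
    mean_width_independent = 0.06, mean_width_paired = 0.05,
    width_ratio = 1.2,
    var_ratio_independent = 1.1, var_ratio_paired = 1.0,
    n_replicates_used = 100L, n_invalid = 0L
  )
  s <- summarize_grid(fake)
  row <- s$overall[s$overall$quantity == "coverage_independent", ]
  expect_equal(c(row$q25, row$median, row$q75), c(1.5, 2, 2.5))
  # a single scenario: medians equal its values
  s1 <- summarize_grid(fake[1, ])
  expect_equal(
    s1$overall$median[s1$overall$quantity == "width_ratio"], 1.2
  )
  expect_null(s$type1_table)
})

test_that("tables round-trip to disk with a seed-bearing manifest, reproducibly", {
  specs <- list(
    scenario_spec("independent_bernoulli", "weak", 0.29, 0,
      n_initial = 1500L, n_replicates = 25L
    )
  )
  res <- run_grid(specs, master_seed = 9, m = 1e5)
  summ <- summarize_grid(res)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_tables(summ, d1, metrics = res)
  f2 <- write_tables(summ, d2, metrics = res)
  expect_true(all(file.exists(f1)))
  # round-trip of the type-I table
  back <- read.table(file.path(d1, "type1_error.tsv"),
    header = TRUE, sep = "\t"
  )
  expect_equal(back$type1_mcnemar, summ$type1_table$type1_mcnemar)
  manifest <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(manifest$master_seed, 9)
  # identical content for identical inputs
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})

test_that("run configurations parse presets, overrides and coefficient tables", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "preset: desk_null",
    "master_seed: 7",
    "n_replicates: 50",
    "caliper_multiplier: 0.25"
  ), cfg)
  rc <- read_run_config(cfg)
  expect_length(rc$specs, 20)
  expect_equal(rc$specs[[1]]$n_replicates, 50L)
  expect_equal(rc$master_seed, 7L)
  expect_equal(rc$caliper_multiplier, 0.25)

  cfg2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "scenarios:",
    "  - covariate_scenario: mixed2",
    "    selection_strength: strong",
    "    baseline_outcome_prob: 0.15",
    "    target_rd: -0.1"
  ), cfg2)
  rc2 <- read_run_config(cfg2)
  expect_length(rc2$specs, 1)
  expect_equal(rc2$specs[[1]]$covariate_scenario, "mixed2")
  expect_equal(rc2$specs[[1]]$n_initial, 1000L)

  tab <- calibrate_grid(list(scenario_spec("mixed2", "weak", 0.29, 0)),
    m = 5e4, seed = 54
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coefficients(tab, f)
  expect_equal(read_coefficients(f), tab, tolerance = 1e-12)
})

test_that("presets define the documented run shapes", {
  full <- run_preset("full")
  expect_length(full$specs, 100)
  expect_equal(full$specs[[1]]$n_replicates, 1825L)
  desk <- run_preset("desk_grid")
  expect_length(desk$specs, 100)
  weak_n <- vapply(
    Filter(function(s) s$selection_strength == "weak", desk$specs),
    function(s) s$n_initial, integer(1)
  )
  expect_true(all(weak_n == 2500L))
  expect_equal(desk$specs[[1]]$n_replicates, 150L)
  expect_length(run_preset("desk_null")$specs, 20)
})
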