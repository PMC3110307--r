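#' Target risk differences of the study grid
#' @export
target_rds <- c(0, -0.02, -0.05, -0.10, -0.15)

#' Construct a scenario specification
#'
#' One cell of the simulation grid: a covariate scenario, a
#' treatment-selection strength, a baseline outcome probability, a target
#' ATT risk difference, and sizes. The weak-selection design simulates
#' cohorts of 10 000 subjects directly; the strong-selection design starts
#' from 1000 subjects and enlarges the control reservoir with 10 extra
#' independent-outcome copies of every untreated subject.
#'
#' @param covariate_scenario one of [covariate_scenarios].
#' @param selection_strength `"weak"` or `"strong"`.
#' @param baseline_outcome_prob marginal outcome probability if untreated
#'   (0.29 or 0.15 in the study grid).
#' @param target_rd target ATT risk difference (non-positive).
#' @param n_initial initial cohort size; defaults to 10 000 (weak) or
#'   1000 (strong).
#' @param control_copies extra copies per untreated subject; defaults to 0
#'   (weak) or 10 (strong). Must be 0 under weak selection.
#' @param n_replicates number of Monte Carlo replicates (default 1825).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(covariate_scenario,
                          selection_strength = c("weak", "strong"),
                          baseline_outcome_prob = 0.29,
                          target_rd = 0,
                          n_initial = NULL,
                          control_copies = NULL,
                          n_replicates = 1825L) {
  covariate_scenario <- match.arg(covariate_scenario, covariate_scenarios)
  selection_strength <- match.arg(selection_strength)
  stopifnot(
    baseline_outcome_prob > 0, baseline_outcome_prob < 1,
    target_rd <= 0, target_rd > -1, n_replicates >= 1
  )
  if (is.null(n_initial)) {
    n_initial <- if (selection_strength == "weak") 10000L else 1000L
  }
  if (is.null(control_copies)) {
    control_copies <- if (selection_strength == "weak") 0L else 10L
  }
  if (control_copies > 0L && selection_strength == "weak") {
    stop("control_copies > 0 is only used with strong treatment selection")
  }
  structure(
    list(
      covariate_scenario = covariate_scenario,
      selection_strength = selection_strength,
      baseline_outcome_prob = baseline_outcome_prob,
      target_rd = target_rd,
      n_initial = as.integer(n_initial),
      control_copies = as.integer(control_copies),
      n_replicates = as.integer(n_replicates)
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario: %s, %s selection, P0=%.2f, target RD=%.2f, n=%d (+%d control copies), %d replicates\n",
    x$covariate_scenario, x$selection_strength, x$baseline_outcome_prob,
    x$target_rd, x$n_initial, x$control_copies, x$n_replicates
  ))
  invisible(x)
}

#' Canonical index of a scenario within the 100-cell grid
#'
#' The grid is ordered in four sets of 25 — (weak, 0.29), (weak, 0.15),
#' (strong, 0.29), (strong, 0.15) — each running over the five covariate
#' scenarios and, within each, the five target risk differences. The index
#' seeds the per-replicate random streams, so every scenario is
#' independently reproducible.
#'
#' @param spec a `scenario_spec`.
#' @return integer in 1..100.
#' @export
scenario_index <- function(spec) {
  s <- 2L * (spec$selection_strength == "strong") +
    (abs(spec$baseline_outcome_prob - 0.15) < 1e-9)
  j <- match(spec$covariate_scenario, covariate_scenarios) - 1L
  k <- which.min(abs(target_rds - spec$target_rd)) - 1L
  as.integer(s * 25L + j * 5L + k + 1L)
}

#' The full 100-scenario study grid
#'
#' @param n_replicates replicates per scenario (default 1825).
#' @return a list of 100 `scenario_spec` objects in canonical order.
#' @export
scenario_grid <- function(n_replicates = 1825L) {
  specs <- list()
  for (set in list(
    c("weak", 0.29), c("weak", 0.15), c("strong", 0.29), c("strong", 0.15)
  )) {
    for (cov in covariate_scenarios) {
      for (rd in target_rds) {
        specs[[length(specs) + 1L]] <- scenario_spec(
          cov, set[[1]],
          baseline_outcome_prob = as.numeric(set[[2]]), target_rd = rd,
          n_replicates = n_replicates
        )
      }
    }
  }
  specs
}

#' The 20 null scenarios of the grid
#'
#' @param n_replicates replicates per scenario.
#' @return list of the `scenario_spec`s with target risk difference 0.
#' @export
null_grid <- function(n_replicates = 1825L) {
  Filter(function(s) s$target_rd == 0, scenario_grid(n_replicates))
}

# Deterministic per-replicate seed derived from (master seed, scenario
# index, replicate index); kept below 2^31 - 1. Replicates are independent,
# so scenario results are identical whether run serially or concurrently.
replicate_seed <- function(master_seed, scenario_index, replicate) {
  s <- (as.numeric(master_seed) %% 2147483647) * 48271 +
    as.numeric(scenario_index) * 1299721 +
    as.numeric(replicate) * 15485863
  as.integer(s %% 2147483647)
}

#' Run one Monte Carlo replicate
#'
#' Simulates a cohort from the calibrated data-generating process (enlarging
#' the control reservoir if the spec requires), estimates the propensity
#' score, computes the caliper, matches greedily on the logit propensity
#' score, and performs paired and independent-samples inference on the
#' matched pairs. Deterministic given `(spec, coeffs, seed)`. Replicates
#' whose propensity model fails to converge or whose matched sample is empty
#' are flagged invalid rather than erroring.
#'
#' @param spec a `scenario_spec`.
#' @param coeffs a fully calibrated `coefficient_set` for this spec.
#' @param seed integer seed for this replicate.
#' @param caliper_multiplier caliper multiplier (default 0.2).
#' @return a one-row data frame with columns `valid`, `converged`,
#'   `n_pairs`, `matched_pct`, `rd`, `se_independent`, `se_paired`,
#'   `ci_ind_lower`, `ci_ind_upper`, `ci_par_lower`, `ci_par_upper`,
#'   `p_pearson`, `p_mcnemar`.
#' @export
run_replicate <- function(spec, coeffs, seed, caliper_multiplier = 0.2) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(coeffs, "coefficient_set"))
  set.seed(seed)
  cohort <- simulate_cohort(spec$covariate_scenario, spec$n_initial, coeffs)
  if (spec$control_copies > 0L) {
    cohort <- augment_controls(cohort, spec$control_copies)
  }
  invalid <- function(converged) {
    data.frame(
      valid = FALSE, converged = converged, n_pairs = 0L,
      matched_pct = NA_real_, rd = NA_real_,
      se_independent = NA_real_, se_paired = NA_real_,
      ci_ind_lower = NA_real_, ci_ind_upper = NA_real_,
      ci_par_lower = NA_real_, ci_par_upper = NA_real_,
      p_pearson = NA_real_, p_mcnemar = NA_real_
    )
  }
  fit <- fit_propensity(cohort$X, cohort$Z)
  if (!fit$converged) {
    warning("propensity model did not converge; replicate excluded")
    return(invalid(FALSE))
  }
  caliper <- compute_caliper(fit$logit_ps, cohort$Z, caliper_multiplier)
  matched <- greedy_match(fit$logit_ps, cohort$Z, caliper)
  if (nrow(matched$pairs) == 0L) {
    warning("empty matched sample; replicate excluded")
    return(invalid(TRUE))
  }
  tab <- paired_table(matched, cohort$Y)
  inf <- rd_inference(tab)
  data.frame(
    valid = TRUE, converged = TRUE, n_pairs = tab$n,
    matched_pct = matched_percentage(matched), rd = inf$rd,
    se_independent = inf$se_independent, se_paired = inf$se_paired,
    ci_ind_lower = inf$ci_independent[["lower"]],
    ci_ind_upper = inf$ci_independent[["upper"]],
    ci_par_lower = inf$ci_paired[["lower"]],
    ci_par_upper = inf$ci_paired[["upper"]],
    p_pearson = inf$p_pearson, p_mcnemar = inf$p_mcnemar
  )
}

#' Run all replicates of one scenario and compute its evaluation metrics
#'
#' Runs `n_replicates` independent replicates and summarises them into the
#' study's evaluation metrics: empirical type I error rates (null scenarios
#' only, rejection at p < 0.05 strictly), empirical coverage of the 95 per
#' cent Wald intervals, mean interval widths and their ratio, and the
#' variance ratios `(mean estimated SE / empirical SD of the risk
#' difference)^2` for each method.
#'
#' @param spec a `scenario_spec`.
#' @param coeffs calibrated `coefficient_set` for this spec.
#' @param master_seed master seed; per-replicate seeds are derived from it
#'   together with the scenario index.
#' @param n_replicates number of replicates (defaults to `spec$n_replicates`).
#' @param caliper_multiplier caliper multiplier.
#' @param keep_records also return the per-replicate records.
#' @return an object of class `scenario_metrics` (a list; see fields in the
#'   description), with the per-replicate data frame in `$records` when
#'   `keep_records = TRUE`.
#' @export
run_scenario <- function(spec, coeffs, master_seed = 1L,
                         n_replicates = spec$n_replicates,
                         caliper_multiplier = 0.2,
                         keep_records = FALSE) {
  stopifnot(n_replicates >= 2)
  idx <- scenario_index(spec)
  records <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    records[[r]] <- run_replicate(
      spec, coeffs, replicate_seed(master_seed, idx, r), caliper_multiplier
    )
  }
  records <- do.call(rbind, records)
  metrics <- scenario_metrics(spec, records)
  if (keep_records) metrics$records <- records
  metrics
}

# Reduce per-replicate records to the scenario-level evaluation metrics.
scenario_metrics <- function(spec, records) {
  ok <- records[records$valid, , drop = FALSE]
  n_total <- nrow(records)
  if (nrow(ok) < n_total / 2) {
    stop(sprintf(
      "scenario failed: %d of %d replicates invalid",
      n_total - nrow(ok), n_total
    ))
  }
  is_null <- spec$target_rd == 0
  covers <- function(lo, hi) mean(lo <= spec$target_rd & spec$target_rd <= hi)
  mw_i <- mean(ok$ci_ind_upper - ok$ci_ind_lower)
  mw_p <- mean(ok$ci_par_upper - ok$ci_par_lower)
  emp_sd <- stats::sd(ok$rd)
  structure(
    list(
      covariate_scenario = spec$covariate_scenario,
      selection_strength = spec$selection_strength,
      baseline_outcome_prob = spec$baseline_outcome_prob,
      target_rd = spec$target_rd,
      scenario_index = scenario_index(spec),
      mean_matched_pct = mean(ok$matched_pct),
      type1_pearson = if (is_null) mean(ok$p_pearson < 0.05) else NA_real_,
      type1_mcnemar = if (is_null) mean(ok$p_mcnemar < 0.05) else NA_real_,
      coverage_independent = covers(ok$ci_ind_lower, ok$ci_ind_upper),
      coverage_paired = covers(ok$ci_par_lower, ok$ci_par_upper),
      mean_width_independent = mw_i,
      mean_width_paired = mw_p,
      width_ratio = mw_i / mw_p,
      var_ratio_independent = (mean(ok$se_independent) / emp_sd)^2,
      var_ratio_paired = (mean(ok$se_paired) / emp_sd)^2,
      n_replicates_used = nrow(ok),
      n_invalid = n_total - nrow(ok)
    ),
    class = "scenario_metrics"
  )
}

#' @export
print.scenario_metrics <- function(x, ...) {
  cat(sprintf(
    "Scenario metrics [%s, %s, P0=%.2f, RD=%.2f]: %d replicates\n",
    x$covariate_scenario, x$selection_strength, x$baseline_outcome_prob,
    x$target_rd, x$n_replicates_used
  ))
  if (!is.na(x$type1_mcnemar)) {
    cat(sprintf(
      "  type I error: Pearson %.4f, McNemar %.4f\n",
      x$type1_pearson, x$type1_mcnemar
    ))
  }
  cat(sprintf(
    "  matched %.1f%% | coverage ind %.3f / paired %.3f | width ratio %.3f | var ratio ind %.3f / paired %.3f\n",
    x$mean_matched_pct, x$coverage_independent, x$coverage_paired,
    x$width_ratio, x$var_ratio_independent, x$var_ratio_paired
  ))
  invisible(x)
}

#' Monte Carlo significance bounds for an empirical proportion
#'
#' The band outside which an empirical rate computed from `n_reps`
#' replicates is statistically significantly different from its nominal
#' value: `nominal +/- 1.96 * sqrt(nominal * (1 - nominal) / n_reps)`. At
#' 1825 replicates the band for a 0.05 type I error rate is (0.04, 0.06) and
#' for 0.95 coverage it is (0.94, 0.96).
#'
#' @param nominal nominal rate in (0, 1).
#' @param n_reps number of replicates.
#' @return list with `nominal`, `n_reps`, `lower`, `upper`.
#' @export
mc_significance_bounds <- function(nominal, n_reps) {
  stopifnot(nominal > 0, nominal < 1, n_reps >= 2)
  half <- 1.96 * sqrt(nominal * (1 - nominal) / n_reps)
  list(nominal = nominal, n_reps = n_reps,
       lower = nominal - half, upper = nominal + half)
}
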