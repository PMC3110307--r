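# Grid-level calibration and execution: the scenario harness proper.

# Monotone root for the intercept given a fixed linear-predictor sample.
intercept_from_eta <- function(eta, target, tol = 1e-4) {
  f <- function(a0) mean(stats::plogis(a0 + eta)) - target
  sol <- stats::uniroot(f, c(-30, 30), tol = 1e-8, maxiter = 200L)
  if (abs(f(sol$root)) > tol) stop("intercept calibration did not converge")
  sol$root
}

# Monotone root for beta given treatment-probability weights and the
# untreated outcome linear predictor.
beta_from_sample <- function(w, eta_o, target_rd, tol = 1e-4) {
  if (target_rd == 0) {
    return(0)
  }
  p0 <- stats::plogis(eta_o)
  sw <- sum(w)
  f <- function(beta) {
    sum(w * (stats::plogis(eta_o + beta) - p0)) / sw - target_rd
  }
  sol <- stats::uniroot(f, c(-30, 0), tol = 1e-8, maxiter = 200L)
  if (abs(f(sol$root)) > tol) stop("beta calibration did not converge")
  sol$root
}

#' Calibrate coefficient sets for a collection of scenarios
#'
#' Calibrates intercepts and treatment effects for every scenario in the
#' grid. Scenarios sharing a covariate scenario, selection strength and
#' baseline outcome probability share one calibration sample, so the
#' intercepts are solved once per combination and only \eqn{\beta} varies
#' with the target risk difference.
#'
#' @param specs list of `scenario_spec`s (default: the full 100-cell grid).
#' @param treated_fraction target marginal proportion treated.
#' @param allocation covariate-to-coefficient allocation.
#' @param m calibration sample size.
#' @param seed calibration-sample seed (fixed by default for reproducible
#'   constants).
#' @param tol tolerance on the probability / risk-difference scale.
#' @return a data frame with one row per scenario: identifiers plus
#'   `alpha0_treat`, `alpha0_outcome`, `beta` and the allocation string.
#' @export
calibrate_grid <- function(specs = scenario_grid(),
                           treated_fraction = 0.25,
                           allocation = default_allocation(),
                           m = 1e6, seed = 904200L, tol = 1e-4) {
  key <- vapply(specs, function(s) {
    paste(s$covariate_scenario, s$selection_strength,
      s$baseline_outcome_prob,
      sep = "|"
    )
  }, character(1))
  rows <- vector("list", length(specs))
  for (k in unique(key)) {
    members <- which(key == k)
    s1 <- specs[[members[1]]]
    coeffs <- build_coefficients(s1$selection_strength, allocation)
    set.seed(seed)
    X <- generate_covariates(s1$covariate_scenario, m)
    eta <- drop(X %*% coeffs$slopes)
    a0t <- intercept_from_eta(eta, treated_fraction, tol)
    a0o <- intercept_from_eta(eta, s1$baseline_outcome_prob, tol)
    w <- stats::plogis(a0t + eta)
    betas <- new.env()
    for (i in members) {
      s <- specs[[i]]
      rd_key <- as.character(s$target_rd)
      if (is.null(betas[[rd_key]])) {
        betas[[rd_key]] <- beta_from_sample(w, a0o + eta, s$target_rd, tol)
      }
      rows[[i]] <- data.frame(
        scenario_index = scenario_index(s),
        covariate_scenario = s$covariate_scenario,
        selection_strength = s$selection_strength,
        baseline_outcome_prob = s$baseline_outcome_prob,
        target_rd = s$target_rd,
        alpha0_treat = a0t,
        alpha0_outcome = a0o,
        beta = betas[[rd_key]],
        allocation = paste(allocation, collapse = ",")
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$scenario_index), , drop = FALSE]
}

# Rebuild a calibrated coefficient_set from one row of a calibration table.
coefficients_from_row <- function(row) {
  coeffs <- build_coefficients(
    row$selection_strength,
    strsplit(row$allocation, ",", fixed = TRUE)[[1]]
  )
  coeffs$alpha0_treat <- row$alpha0_treat
  coeffs$alpha0_outcome <- row$alpha0_outcome
  coeffs$beta <- row$beta
  coeffs
}

#' @export
as.data.frame.scenario_metrics <- function(x, ...) {
  data.frame(
    covariate_scenario = x$covariate_scenario,
    selection_strength = x$selection_strength,
    baseline_outcome_prob = x$baseline_outcome_prob,
    target_rd = x$target_rd,
    scenario_index = x$scenario_index,
    mean_matched_pct = x$mean_matched_pct,
    type1_pearson = x$type1_pearson,
    type1_mcnemar = x$type1_mcnemar,
    coverage_independent = x$coverage_independent,
    coverage_paired = x$coverage_paired,
    mean_width_independent = x$mean_width_independent,
    mean_width_paired = x$mean_width_paired,
    width_ratio = x$width_ratio,
    var_ratio_independent = x$var_ratio_independent,
    var_ratio_paired = x$var_ratio_paired,
    n_replicates_used = x$n_replicates_used,
    n_invalid = x$n_invalid
  )
}

#' Run a collection of scenarios
#'
#' Calibrates (or reuses) coefficient sets and runs every scenario,
#' returning one row of evaluation metrics per scenario. Fully deterministic
#' given the grid, the calibration table and `master_seed`.
#'
#' @param specs list of `scenario_spec`s.
#' @param coeffs_table optional precomputed calibration table from
#'   [calibrate_grid()]; calibrated on the fly when `NULL`.
#' @param master_seed master seed for replicate streams.
#' @param n_replicates optional override of each spec's replicate count.
#' @param caliper_multiplier caliper multiplier.
#' @param m calibration sample size (when calibrating on the fly).
#' @param calibration_seed calibration-sample seed.
#' @param allocation covariate-to-coefficient allocation.
#' @param verbose print per-scenario progress lines.
#' @return a data frame of scenario metrics with the calibration table
#'   attached as attribute `"coefficients"` and the master seed as
#'   attribute `"master_seed"`.
#' @export
run_grid <- function(specs, coeffs_table = NULL, master_seed = 1L,
                     n_replicates = NULL, caliper_multiplier = 0.2,
                     m = 1e6, calibration_seed = 904200L,
                     allocation = default_allocation(), verbose = FALSE) {
  if (is.null(coeffs_table)) {
    coeffs_table <- calibrate_grid(
      specs,
      allocation = allocation, m = m, seed = calibration_seed
    )
  }
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    if (!is.null(n_replicates)) spec$n_replicates <- as.integer(n_replicates)
    row <- coeffs_table[coeffs_table$scenario_index == scenario_index(spec), ]
    if (nrow(row) != 1L) {
      stop("no unique calibration row for scenario ", scenario_index(spec))
    }
    metrics <- run_scenario(
      spec, coefficients_from_row(row[1, ]),
      master_seed = master_seed,
      caliper_multiplier = caliper_multiplier
    )
    if (verbose) {
      message(sprintf(
        "[%3d/%d] %s %s P0=%.2f RD=%+.2f  matched %.1f%%",
        i, length(specs), spec$covariate_scenario, spec$selection_strength,
        spec$baseline_outcome_prob, spec$target_rd, metrics$mean_matched_pct
      ))
    }
    out[[i]] <- as.data.frame(metrics)
  }
  res <- do.call(rbind, out)
  attr(res, "coefficients") <- coeffs_table
  attr(res, "master_seed") <- master_seed
  res
}

set_label <- function(strength, p0) {
  sprintf("%.2f outcome probability, %s treatment-selection model", p0, strength)
}

#' Summarise grid metrics into the study's presentation tables
#'
#' Produces the type-I error table over the null scenarios, one
#' coverage/width/variance-ratio table per (selection strength, baseline
#' outcome probability) set, and cross-scenario medians and quartiles
#' (linear interpolation between order statistics) of coverage, width ratio
#' and variance ratios per method, plus counts of scenarios whose empirical
#' rates fall outside the Monte Carlo significance bands.
#'
#' @param metrics a metrics data frame from [run_grid()] (or rbind of
#'   [as.data.frame()]'d `scenario_metrics`).
#' @return an object of class `grid_summary`: list with `type1_table`,
#'   `coverage_tables` (named list per set) and `overall` (data frame of
#'   summary statistics).
#' @export
summarize_grid <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  nulls <- metrics[!is.na(metrics$type1_mcnemar), , drop = FALSE]
  type1_table <- if (nrow(nulls)) {
    data.frame(
      set = set_label(nulls$selection_strength, nulls$baseline_outcome_prob),
      covariate_scenario = nulls$covariate_scenario,
      mean_matched_pct = nulls$mean_matched_pct,
      type1_pearson = nulls$type1_pearson,
      type1_mcnemar = nulls$type1_mcnemar
    )
  } else {
    NULL
  }
  sets <- unique(metrics[, c("selection_strength", "baseline_outcome_prob")])
  coverage_tables <- list()
  for (i in seq_len(nrow(sets))) {
    sub <- metrics[
      metrics$selection_strength == sets$selection_strength[i] &
        metrics$baseline_outcome_prob == sets$baseline_outcome_prob[i], ,
      drop = FALSE
    ]
    coverage_tables[[set_label(
      sets$selection_strength[i], sets$baseline_outcome_prob[i]
    )]] <- sub[, c(
      "covariate_scenario", "target_rd",
      "coverage_independent", "coverage_paired",
      "mean_width_independent", "mean_width_paired", "width_ratio",
      "var_ratio_independent", "var_ratio_paired"
    )]
  }
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  overall_of <- function(name, x) {
    qq <- q(x)
    data.frame(
      quantity = name, q25 = qq[1], median = qq[2], q75 = qq[3],
      min = min(x), max = max(x)
    )
  }
  overall <- rbind(
    overall_of("coverage_independent", metrics$coverage_independent),
    overall_of("coverage_paired", metrics$coverage_paired),
    overall_of("width_ratio", metrics$width_ratio),
    overall_of("var_ratio_independent", metrics$var_ratio_independent),
    overall_of("var_ratio_paired", metrics$var_ratio_paired)
  )
  cov_band <- mc_significance_bounds(0.95, max(metrics$n_replicates_used))
  outside <- data.frame(
    quantity = c(
      "coverage_independent_outside_band",
      "coverage_paired_outside_band",
      if (nrow(nulls)) "type1_pearson_outside_band",
      if (nrow(nulls)) "type1_mcnemar_outside_band"
    ),
    count = c(
      sum(metrics$coverage_independent < cov_band$lower |
        metrics$coverage_independent > cov_band$upper),
      sum(metrics$coverage_paired < cov_band$lower |
        metrics$coverage_paired > cov_band$upper),
      if (nrow(nulls)) {
        t1_band <- mc_significance_bounds(0.05, max(nulls$n_replicates_used))
        c(
          sum(nulls$type1_pearson < t1_band$lower |
            nulls$type1_pearson > t1_band$upper),
          sum(nulls$type1_mcnemar < t1_band$lower |
            nulls$type1_mcnemar > t1_band$upper)
        )
      }
    )
  )
  structure(
    list(
      type1_table = type1_table,
      coverage_tables = coverage_tables,
      overall = overall,
      outside_bands = outside,
      n_scenarios = nrow(metrics)
    ),
    class = "grid_summary"
  )
}

#' @export
print.grid_summary <- function(x, ...) {
  cat(sprintf("Grid summary over %d scenarios\n", x$n_scenarios))
  print(x$overall, row.names = FALSE)
  cat("Scenarios outside Monte Carlo significance bands:\n")
  print(x$outside_bands, row.names = FALSE)
  invisible(x)
}

#' Write summary tables and a run manifest to disk
#'
#' Writes tab-delimited files with fixed column order: the type-I error
#' table, one coverage table per scenario set, the overall summary, the
#' counts outside the significance bands, the calibration table (when
#' attached to the metrics), and a YAML manifest recording the master seed,
#' package version and a checksum of the configuration. Output is
#' byte-identical across runs with the same inputs.
#'
#' @param summary a `grid_summary`.
#' @param path output directory (created if missing).
#' @param metrics optional metrics data frame from [run_grid()]; its
#'   attached calibration table and master seed are recorded.
#' @return invisibly, the vector of files written.
#' @export
write_tables <- function(summary, path, metrics = NULL) {
  stopifnot(inherits(summary, "grid_summary"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    f <- file.path(path, name)
    utils::write.table(df, f,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    written <<- c(written, f)
  }
  if (!is.null(summary$type1_table)) wr(summary$type1_table, "type1_error.tsv")
  for (nm in names(summary$coverage_tables)) {
    slug <- gsub("[^a-z0-9]+", "_", tolower(nm))
    wr(summary$coverage_tables[[nm]], paste0("coverage_", slug, ".tsv"))
  }
  wr(summary$overall, "overall_summary.tsv")
  wr(summary$outside_bands, "outside_bands.tsv")
  manifest <- list(
    package = "matchedRD",
    version = as.character(utils::packageVersion("matchedRD")),
    n_scenarios = summary$n_scenarios
  )
  if (!is.null(metrics)) {
    coeffs <- attr(metrics, "coefficients")
    if (!is.null(coeffs)) {
      wr(coeffs, "calibrated_coefficients.tsv")
      manifest$coefficients_checksum <- text_checksum(
        paste(utils::capture.output(utils::write.table(
          coeffs, stdout(),
          sep = "\t", row.names = FALSE
        )), collapse = "\n")
      )
    }
    manifest$master_seed <- attr(metrics, "master_seed")
  }
  mf <- file.path(path, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  written <- c(written, mf)
  invisible(written)
}

# FNV-1a style checksum over a string; avoids binary artefacts in manifests.
text_checksum <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  sprintf("%d", as.integer(h))
}
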