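#' Published reference constants for the independent-normal, weak-selection
#' scenario
#'
#' Intercepts and treatment log-odds ratios originally reported for the
#' data-generating process with independent standard-normal covariates and a
#' weak treatment-selection model: treatment-model intercept giving roughly
#' 25 per cent treated, outcome-model intercept giving a marginal untreated
#' outcome probability of roughly 0.29, and the log-odds ratio \eqn{\beta}
#' inducing each target marginal risk difference among the treated. These are
#' kept for cross-checks; the package recalibrates all constants numerically
#' so that the marginal targets hold exactly under the configured
#' covariate-to-coefficient allocation (the exact allocation behind the
#' published constants is not recoverable).
#'
#' @format A list with elements `alpha0_treat`, `alpha0_outcome` and
#'   `beta` (a named vector keyed by target risk difference).
#' @export
reference_constants <- list(
  alpha0_treat = -1.344090,
  alpha0_outcome = -1.098537,
  beta = c(
    "0" = 0,
    "-0.02" = log(0.90619),
    "-0.05" = log(0.7795362),
    "-0.1" = log(0.6001387),
    "-0.15" = log(0.45292)
  )
)

# Coefficient magnitudes on the log-odds scale: low/medium/high/very-high
# effect sizes for the weak and strong treatment-selection models.
level_values_for <- function(selection_strength) {
  switch(match.arg(selection_strength, c("weak", "strong")),
    weak = c(L = log(1.1), M = log(1.25), H = log(1.5), VH = log(2)),
    strong = c(L = log(1.5), M = log(1.75), H = log(2), VH = log(2.5))
  )
}

#' Default covariate-to-coefficient allocation
#'
#' Assigns each of the ten covariates one of the four coefficient magnitudes
#' (low, medium, high, very-high) in a repeating L, M, H, VH pattern, giving
#' three low, three medium, two high and two very-high covariates. The same
#' allocation is used in the treatment-selection and outcome models, making
#' every covariate a confounder.
#'
#' @return a length-10 character vector of levels in `c("L","M","H","VH")`.
#' @export
default_allocation <- function() {
  rep(c("L", "M", "H", "VH"), length.out = 10L)
}

#' Build a coefficient set for the data-generating process
#'
#' Creates the slope coefficients shared by the treatment-selection and
#' outcome models. Intercepts and the treatment effect \eqn{\beta} are left
#' `NA` until calibrated with [calibrate_intercept()] / [calibrate_beta()]
#' (or [calibrate_scenario()], which does all three).
#'
#' @param selection_strength `"weak"` or `"strong"`. The weak model uses
#'   log odds ratios log(1.1), log(1.25), log(1.5), log(2); the strong model
#'   log(1.5), log(1.75), log(2), log(2.5).
#' @param allocation length-10 vector of levels in `c("L","M","H","VH")`
#'   mapping each covariate to a coefficient magnitude.
#' @return an object of class `coefficient_set`: a list with
#'   `selection_strength`, `level_values`, `allocation`, `slopes`
#'   (length-10 numeric), and `NA` placeholders `alpha0_treat`,
#'   `alpha0_outcome`, `beta`.
#' @examples
#' cs <- build_coefficients("weak")
#' cs$slopes
#' @export
build_coefficients <- function(selection_strength = c("weak", "strong"),
                               allocation = default_allocation()) {
  selection_strength <- match.arg(selection_strength)
  allocation <- as.character(allocation)
  if (length(allocation) != 10L || !all(allocation %in% c("L", "M", "H", "VH"))) {
    stop("allocation must be a length-10 vector of levels L, M, H, VH")
  }
  lv <- level_values_for(selection_strength)
  structure(
    list(
      selection_strength = selection_strength,
      level_values = lv,
      allocation = allocation,
      slopes = unname(lv[allocation]),
      alpha0_treat = NA_real_,
      alpha0_outcome = NA_real_,
      beta = NA_real_
    ),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Coefficient set (", x$selection_strength, " treatment selection)\n",
    sep = ""
  )
  cat("  allocation: ", paste(x$allocation, collapse = " "), "\n", sep = "")
  cat(sprintf(
    "  alpha0_treat = %s, alpha0_outcome = %s, beta = %s\n",
    format(x$alpha0_treat), format(x$alpha0_outcome), format(x$beta)
  ))
  invisible(x)
}

# Calibration sample shared by the intercept and beta solvers: covariates plus
# their linear predictor under the model slopes.
calibration_sample <- function(scenario, slopes, m, seed) {
  if (!is.null(seed)) set.seed(seed)
  X <- generate_covariates(scenario, m)
  list(eta = drop(X %*% slopes))
}

#' Calibrate a logistic-model intercept to a marginal probability
#'
#' Finds the intercept \eqn{\alpha_0} such that the marginal mean of
#' \eqn{\mathrm{expit}(\alpha_0 + X'\alpha)} equals `target_prob`, by
#' monotone root finding over a fixed Monte Carlo calibration sample of `m`
#' covariate draws (common random numbers across candidate intercepts, so the
#' objective is smooth and strictly increasing).
#'
#' @param target_prob target marginal probability in (0, 1): the proportion
#'   treated for the treatment model, or the marginal outcome probability with
#'   everyone untreated for the outcome model.
#' @param slopes length-10 numeric covariate coefficients.
#' @param scenario covariate scenario label (see [covariate_scenarios]).
#' @param m calibration sample size.
#' @param seed seed for the calibration sample; fixed by default so that
#'   calibrated constants are reproducible across runs.
#' @param tol convergence tolerance on the probability scale.
#' @return the calibrated intercept (numeric scalar).
#' @examples
#' # no covariate signal: intercept is just the logit of the target
#' calibrate_intercept(0.25, rep(0, 10), "independent_normal", m = 100)
#' @export
calibrate_intercept <- function(target_prob, slopes, scenario,
                                m = 1e6, seed = 904200L, tol = 1e-4) {
  stopifnot(target_prob > 0, target_prob < 1, length(slopes) == 10L)
  if (all(slopes == 0)) {
    return(stats::qlogis(target_prob))
  }
  samp <- calibration_sample(scenario, slopes, m, seed)
  f <- function(a0) mean(stats::plogis(a0 + samp$eta)) - target_prob
  sol <- stats::uniroot(f, c(-30, 30), tol = 1e-8, maxiter = 200L)
  if (abs(f(sol$root)) > tol) {
    stop(sprintf(
      "intercept calibration did not converge: residual %.3g at alpha0=%.4f",
      f(sol$root), sol$root
    ))
  }
  sol$root
}

#' Calibrate the treatment effect to a marginal ATT risk difference
#'
#' Finds the treatment log-odds ratio \eqn{\beta} in the outcome model such
#' that the marginal risk difference among the treated,
#' \eqn{E[\mathrm{expit}(\alpha_0 + X'\alpha + \beta) -
#' \mathrm{expit}(\alpha_0 + X'\alpha) \mid Z = 1]}, equals `target_rd`.
#' The conditional expectation over treated subjects is computed as a
#' probability-of-treatment weighted average over the calibration sample
#' (the Rao-Blackwellised form of averaging over Bernoulli treatment draws),
#' and the root is found by monotone bracketing: the ATT risk difference is
#' strictly increasing in \eqn{\beta}.
#'
#' @param target_rd target risk difference among the treated, in (-1, 0].
#'   A target of 0 short-circuits to \eqn{\beta = 0}.
#' @param coeffs a `coefficient_set` with both intercepts calibrated.
#' @inheritParams calibrate_intercept
#' @return the calibrated \eqn{\beta} (numeric scalar, non-positive).
#' @export
calibrate_beta <- function(target_rd, coeffs, scenario,
                           m = 1e6, seed = 904200L, tol = 1e-4) {
  stopifnot(inherits(coeffs, "coefficient_set"), target_rd > -1, target_rd <= 0)
  if (is.na(coeffs$alpha0_treat) || is.na(coeffs$alpha0_outcome)) {
    stop("coeffs must have calibrated intercepts before beta calibration")
  }
  if (target_rd == 0) {
    return(0)
  }
  samp <- calibration_sample(scenario, coeffs$slopes, m, seed)
  w <- stats::plogis(coeffs$alpha0_treat + samp$eta)
  p0 <- stats::plogis(coeffs$alpha0_outcome + samp$eta)
  eta_o <- coeffs$alpha0_outcome + samp$eta
  sw <- sum(w)
  att_rd <- function(beta) {
    sum(w * (stats::plogis(eta_o + beta) - p0)) / sw
  }
  f <- function(beta) att_rd(beta) - target_rd
  sol <- stats::uniroot(f, c(-30, 0), tol = 1e-8, maxiter = 200L)
  if (abs(f(sol$root)) > tol) {
    stop(sprintf(
      "beta calibration did not converge: residual %.3g at beta=%.4f",
      f(sol$root), sol$root
    ))
  }
  sol$root
}

#' Calibrate a full coefficient set for one scenario cell
#'
#' Convenience wrapper: builds the slopes for a selection strength and
#' allocation, calibrates the treatment-model intercept to the target
#' proportion treated, the outcome-model intercept to the baseline outcome
#' probability, and \eqn{\beta} to the target ATT risk difference.
#'
#' @param scenario covariate scenario label.
#' @param selection_strength `"weak"` or `"strong"`.
#' @param baseline_outcome_prob marginal outcome probability if everyone were
#'   untreated (0.29 or 0.15 in the study design).
#' @param target_rd target marginal ATT risk difference (non-positive).
#' @param treated_fraction target marginal proportion treated (default 0.25).
#' @param allocation covariate-to-coefficient allocation.
#' @inheritParams calibrate_intercept
#' @return a fully calibrated `coefficient_set`.
#' @examples
#' \donttest{
#' cs <- calibrate_scenario("independent_bernoulli", "weak", 0.29, 0, m = 1e5)
#' cs
#' }
#' @export
calibrate_scenario <- function(scenario, selection_strength,
                               baseline_outcome_prob, target_rd = 0,
                               treated_fraction = 0.25,
                               allocation = default_allocation(),
                               m = 1e6, seed = 904200L, tol = 1e-4) {
  coeffs <- build_coefficients(selection_strength, allocation)
  coeffs$alpha0_treat <- calibrate_intercept(
    treated_fraction, coeffs$slopes, scenario,
    m = m, seed = seed, tol = tol
  )
  coeffs$alpha0_outcome <- calibrate_intercept(
    baseline_outcome_prob, coeffs$slopes, scenario,
    m = m, seed = seed, tol = tol
  )
  coeffs$beta <- calibrate_beta(
    target_rd, coeffs, scenario,
    m = m, seed = seed, tol = tol
  )
  coeffs
}
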