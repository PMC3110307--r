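#' Simulate a confounded cohort
#'
#' Draws covariates, a treatment indicator and a binary outcome from the
#' calibrated data-generating process. Treatment is assigned from the
#' logistic treatment-selection model
#' \eqn{\mathrm{logit}(p_{treat}) = \alpha_{0,treat} + X'\alpha}
#' and the outcome from the logistic outcome model
#' \eqn{\mathrm{logit}(p_{outcome}) = \alpha_{0,outcome} + X'\alpha + \beta Z},
#' with the same slopes \eqn{\alpha} in both models so that every covariate
#' is a confounder.
#'
#' @param scenario covariate scenario label (see [covariate_scenarios]).
#' @param n number of subjects.
#' @param coeffs fully calibrated `coefficient_set`
#'   (see [calibrate_scenario()]).
#' @return an object of class `cohort`: a list with `X` (n x 10 matrix),
#'   `p_treat`, `Z`, `p_outcome`, `Y` (length-n vectors).
#' @export
simulate_cohort <- function(scenario, n, coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (anyNA(c(coeffs$alpha0_treat, coeffs$alpha0_outcome, coeffs$beta))) {
    stop("coefficient set is not fully calibrated")
  }
  X <- generate_covariates(scenario, n)
  eta <- drop(X %*% coeffs$slopes)
  p_treat <- stats::plogis(coeffs$alpha0_treat + eta)
  Z <- stats::rbinom(n, 1L, p_treat)
  p_outcome <- stats::plogis(coeffs$alpha0_outcome + eta + coeffs$beta * Z)
  Y <- stats::rbinom(n, 1L, p_outcome)
  structure(
    list(X = X, p_treat = p_treat, Z = Z, p_outcome = p_outcome, Y = Y),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d subjects, %d treated (%.1f%%), %d events\n",
    length(x$Z), sum(x$Z), 100 * mean(x$Z), sum(x$Y)
  ))
  invisible(x)
}

#' Augment the control pool by replicating untreated subjects
#'
#' Appends `copies` additional copies of every untreated subject, each with
#' identical covariates and outcome probability but an independent fresh
#' Bernoulli outcome draw. Used with the strong treatment-selection model,
#' where the initial cohort is small and the control reservoir is enlarged so
#' that enough treated subjects find a match. Treated subjects are untouched.
#'
#' @param cohort a `cohort`.
#' @param copies number of additional copies per untreated subject
#'   (0 returns the cohort unchanged).
#' @return a `cohort` with `(copies + 1)` times the original untreated count.
#' @export
augment_controls <- function(cohort, copies) {
  stopifnot(inherits(cohort, "cohort"), copies >= 0)
  copies <- as.integer(copies)
  if (copies == 0L) {
    return(cohort)
  }
  untreated <- which(cohort$Z == 0L)
  if (length(untreated) == 0L) {
    stop("cannot augment controls: cohort has no untreated subjects")
  }
  idx <- rep(untreated, copies)
  p_new <- cohort$p_outcome[idx]
  structure(
    list(
      X = rbind(cohort$X, cohort$X[idx, , drop = FALSE]),
      p_treat = c(cohort$p_treat, cohort$p_treat[idx]),
      Z = c(cohort$Z, integer(length(idx))),
      p_outcome = c(cohort$p_outcome, p_new),
      Y = c(cohort$Y, stats::rbinom(length(idx), 1L, p_new))
    ),
    class = "cohort"
  )
}
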