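#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment status on the ten
#' baseline covariates (IRLS, coefficient tolerance 1e-8, at most 100
#' iterations). The linear predictor is the logit of the estimated
#' propensity score, the scale on which matching is performed.
#'
#' @param X n x 10 covariate matrix.
#' @param Z length-n binary treatment indicator.
#' @return an object of class `propensity_fit`: list with `coefficients`
#'   (intercept + 10 slopes), `logit_ps` (length-n linear predictor) and
#'   `converged`.
#' @export
fit_propensity <- function(X, Z) {
  stopifnot(nrow(X) == length(Z))
  if (!any(Z == 1L) || !any(Z == 0L)) {
    stop("both treatment groups must be non-empty")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- stats::glm.fit(
    x = Xd, y = Z, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)
  )
  coefs <- fit$coefficients
  structure(
    list(
      coefficients = coefs,
      logit_ps = drop(Xd %*% coefs),
      converged = isTRUE(fit$converged) && !fit$boundary
    ),
    class = "propensity_fit"
  )
}

#' Caliper width on the logit propensity-score scale
#'
#' The caliper is `multiplier` times the pooled standard deviation of the
#' logit of the propensity score,
#' \eqn{\sqrt{(s_1^2 + s_2^2)/2}}, where \eqn{s_i^2} is the sample variance
#' within treatment group \eqn{i}. The default multiplier 0.2 is the width
#' shown elsewhere to give near-optimal estimation of risk differences.
#'
#' @param logit_ps logit propensity scores for all subjects.
#' @param Z binary treatment indicator.
#' @param multiplier caliper multiplier (default 0.2).
#' @return the caliper width (positive scalar).
#' @export
compute_caliper <- function(logit_ps, Z, multiplier = 0.2) {
  stopifnot(length(logit_ps) == length(Z))
  if (sum(Z == 1L) < 2L || sum(Z == 0L) < 2L) {
    stop("need at least 2 subjects per treatment group")
  }
  pooled <- (stats::var(logit_ps[Z == 1L]) + stats::var(logit_ps[Z == 0L])) / 2
  if (pooled == 0) stop("degenerate data: zero pooled variance of logit PS")
  multiplier * sqrt(pooled)
}

#' Greedy nearest-neighbor caliper matching
#'
#' Forms 1:1 treated-control pairs without replacement on the logit
#' propensity score. Treated subjects are processed in a uniformly random
#' order; each is matched to the closest still-unmatched control, provided
#' the absolute difference in logit propensity scores is within the caliper.
#' Treated subjects with no eligible control remain unmatched. Distance ties
#' between two candidate controls are broken in favour of the lower control
#' index.
#'
#' @param logit_ps logit propensity scores for all subjects.
#' @param Z binary treatment indicator.
#' @param caliper maximum allowed |logit PS difference| within a pair.
#' @param order optional explicit processing order: a permutation of
#'   `seq_len(sum(Z == 1))` over treated subjects (positions within the
#'   treated subset). By default a random permutation is drawn.
#' @return an object of class `matched_sample`: list with `pairs` (two-column
#'   integer matrix of subject indices, columns `treated` and `control`),
#'   `caliper`, and `n_treated_total`.
#' @export
greedy_match <- function(logit_ps, Z, caliper, order = NULL) {
  stopifnot(length(logit_ps) == length(Z), caliper >= 0)
  treated_idx <- which(Z == 1L)
  control_idx <- which(Z == 0L)
  if (is.null(order)) {
    order <- sample.int(length(treated_idx))
  }
  stopifnot(length(order) == length(treated_idx))
  m <- .greedy_match_cpp(
    logit_ps[treated_idx], logit_ps[control_idx],
    as.integer(order) - 1L, caliper
  )
  matched <- which(m >= 0L)
  pairs <- cbind(
    treated = treated_idx[matched],
    control = control_idx[m[matched] + 1L]
  )
  structure(
    list(
      pairs = pairs,
      caliper = caliper,
      n_treated_total = length(treated_idx)
    ),
    class = "matched_sample"
  )
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf(
    "Matched sample: %d pairs (%.1f%% of %d treated), caliper %.4f\n",
    nrow(x$pairs), 100 * nrow(x$pairs) / max(1L, x$n_treated_total),
    x$n_treated_total, x$caliper
  ))
  invisible(x)
}

#' Percentage of treated subjects matched
#'
#' @param matched a `matched_sample`.
#' @return percentage in [0, 100].
#' @export
matched_percentage <- function(matched) {
  stopifnot(inherits(matched, "matched_sample"))
  100 * nrow(matched$pairs) / matched$n_treated_total
}
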