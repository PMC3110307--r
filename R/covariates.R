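#' Covariate scenarios
#'
#' The five joint distributions used for the ten baseline covariates
#' \eqn{X_1, \ldots, X_{10}}:
#' \describe{
#'   \item{`independent_normal`}{ten i.i.d. standard normal covariates.}
#'   \item{`correlated_normal`}{multivariate normal with zero means, unit
#'     variances and exchangeable pairwise correlation 0.25.}
#'   \item{`mixed1`}{\eqn{X_1}-\eqn{X_5} Bernoulli(0.5),
#'     \eqn{X_6}-\eqn{X_{10}} standard normal.}
#'   \item{`mixed2`}{\eqn{X_1}-\eqn{X_9} Bernoulli(0.5), \eqn{X_{10}}
#'     standard normal.}
#'   \item{`independent_bernoulli`}{ten i.i.d. Bernoulli(0.5) covariates.}
#' }
#'
#' @format A character vector of the five scenario labels.
#' @export
covariate_scenarios <- c(
  "independent_normal", "correlated_normal",
  "mixed1", "mixed2", "independent_bernoulli"
)

#' Generate baseline covariates
#'
#' Draws an \eqn{n \times 10} matrix of baseline covariates under one of the
#' five covariate scenarios (see [covariate_scenarios]).
#'
#' @param scenario one of [covariate_scenarios].
#' @param n number of subjects (at least 2).
#' @return an `n` by 10 numeric matrix with columns `X1`..`X10`.
#' @examples
#' X <- generate_covariates("mixed1", 100)
#' colMeans(X)
#' @export
generate_covariates <- function(scenario, n) {
  scenario <- match.arg(scenario, covariate_scenarios)
  if (n < 2) stop("n must be at least 2")
  p <- 10L
  X <- switch(scenario,
    independent_normal = matrix(stats::rnorm(n * p), n, p),
    correlated_normal = {
      # exchangeable correlation 0.25, unit variances, via Cholesky factor
      S <- matrix(0.25, p, p)
      diag(S) <- 1
      matrix(stats::rnorm(n * p), n, p) %*% chol(S)
    },
    mixed1 = cbind(
      matrix(stats::rbinom(n * 5L, 1L, 0.5), n, 5L),
      matrix(stats::rnorm(n * 5L), n, 5L)
    ),
    mixed2 = cbind(
      matrix(stats::rbinom(n * 9L, 1L, 0.5), n, 9L),
      stats::rnorm(n)
    ),
    independent_bernoulli = matrix(stats::rbinom(n * p, 1L, 0.5), n, p)
  )
  colnames(X) <- paste0("X", seq_len(p))
  X
}
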