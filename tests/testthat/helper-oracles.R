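# Independent oracles used across tests. These deliberately re-derive results
# by brute force or textbook formulas, never by calling the package's own
# implementation path.

# Step-by-step replay of the greedy matching rule: process treated subjects
# in the given order; each takes the closest available control within the
# caliper, ties going to the lower control index.
greedy_match_bruteforce <- function(ps_treated, ps_control, order, caliper) {
  available <- rep(TRUE, length(ps_control))
  match <- rep(NA_integer_, length(ps_treated))
  for (i in order) {
    if (!any(available)) break
    cand <- which(available)
    d <- abs(ps_control[cand] - ps_treated[i])
    best <- cand[d == min(d)]
    best <- min(best) # lower index on ties
    if (abs(ps_control[best] - ps_treated[i]) <= caliper) {
      match[i] <- best
      available[best] <- FALSE
    }
  }
  match
}

# Textbook shortcut for the Pearson chi-squared statistic of a 2x2 table.
pearson_2x2_shortcut <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Grid search for the intercept hitting a target marginal probability:
# coarse-to-fine scan over candidate intercepts on an independently drawn
# covariate sample.
intercept_gridsearch <- function(target, slopes, scenario, m, seed) {
  set.seed(seed)
  X <- generate_covariates(scenario, m)
  eta <- drop(X %*% slopes)
  lo <- -10; hi <- 10
  for (step in c(0.1, 0.01, 0.001, 1e-4)) {
    grid <- seq(lo, hi, by = step)
    prev <- vapply(grid, function(a0) mean(plogis(a0 + eta)), numeric(1))
    best <- which.min(abs(prev - target))
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
  }
  (lo + hi) / 2
}

# Grid search for the treatment log-odds ratio hitting a target ATT risk
# difference, averaging over Bernoulli-drawn treated subjects.
beta_gridsearch <- function(target_rd, a0t, a0o, slopes, scenario, m, seed) {
  set.seed(seed)
  X <- generate_covariates(scenario, m)
  eta <- drop(X %*% slopes)
  Z <- rbinom(m, 1L, plogis(a0t + eta))
  eta_o <- (a0o + eta)[Z == 1L]
  lo <- -5; hi <- 0
  for (step in c(0.05, 0.005, 5e-4, 5e-5)) {
    grid <- seq(lo, hi, by = step)
    rd <- vapply(grid, function(b) mean(plogis(eta_o + b) - plogis(eta_o)),
      numeric(1)
    )
    best <- which.min(abs(rd - target_rd))
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
  }
  (lo + hi) / 2
}

# Random paired 2x2 tables for property-style tests.
random_paired_tables <- function(k, max_count = 200L) {
  lapply(seq_len(k), function(i) {
    counts <- rmultinom(1L, sample.int(max_count, 1L) + 3L,
      prob = runif(4, 0.05, 1)
    )[, 1]
    new_paired_table(counts[1], counts[2], counts[3], counts[4])
  })
}

# Standardized difference of one covariate between treatment groups.
std_diff <- function(x, z) {
  m1 <- mean(x[z == 1]); m0 <- mean(x[z == 0])
  s <- sqrt((var(x[z == 1]) + var(x[z == 0])) / 2)
  if (s == 0) 0 else abs(m1 - m0) / s
}
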