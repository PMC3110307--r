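test_that("paired tables classify pairs correctly", {
  m <- structure(
    list(
      pairs = cbind(treated = 1:4, control = 5:8),
      caliper = 1, n_treated_total = 4L
    ),
    class = "matched_sample"
  )
  #            (1,1)  (1,0)  (0,1)  (0,0)
  Y <- c(1, 1, 0, 0, 1, 0, 1, 0)
  t <- paired_table(m, Y)
  expect_equal(c(t$a, t$b, t$c, t$d, t$n), c(1, 1, 1, 1, 4))

  Y0 <- rep(0, 8)
  t0 <- paired_table(m, Y0)
  expect_equal(c(t0$a, t0$b, t0$c), c(0, 0, 0))
  expect_equal(t0$d, 4)

  empty <- m
  empty$pairs <- m$pairs[0, , drop = FALSE]
  expect_error(paired_table(empty, Y), "empty")
})

test_that("risk difference and event proportions follow the counts", {
  t <- new_paired_table(10, 20, 5, 65)
  expect_equal((t$a + t$b) / t$n, 0.30)
  expect_equal((t$a + t$c) / t$n, 0.15)
  expect_equal(risk_difference(t), 0.15)
  expect_equal(risk_difference(new_paired_table(3, 7, 7, 3)), 0)
  # concordant pairs carry no effect
  expect_equal(
    risk_difference(new_paired_table(10 + 50, 20, 5, 65 + 50)),
    (20 - 5) / 200
  )
})

test_that("variance estimators match hand computations", {
  # p_T = 0.3, p_C = 0.2, N = 100
  t <- new_paired_table(10, 20, 10, 60)
  expect_equal(var_independent(t), (0.21 + 0.16) / 100)
  expect_equal(var_independent(new_paired_table(0, 0, 0, 10)), 0)
  # maximal at p_T = p_C = 0.5
  expect_equal(var_independent(new_paired_table(25, 25, 25, 25)), 0.005)
  # paired formula ((b + c) - (c - b)^2 / n) / n^2
  expect_equal(var_paired(new_paired_table(5, 10, 20, 65)), 0.0029)
  expect_equal(var_paired(new_paired_table(4, 0, 0, 6)), 0)
  # worked identity: (40,10,20,30)
  t2 <- new_paired_table(40, 10, 20, 30)
  expect_equal(var_independent(t2), 0.0049)
  expect_equal(var_paired(t2), 0.0029)
  expect_equal(var_independent(t2) - var_paired(t2), 2 * (1200 - 200) / 1e6)
})

test_that("variance decomposition identity holds over random tables", {
  set.seed(41)
  for (t in random_paired_tables(10000)) {
    diff <- var_independent(t) - var_paired(t)
    expect_equal(diff, 2 * (t$a * t$d - t$b * t$c) / t$n^3,
      tolerance = 1e-12
    )
  }
})

test_that("McNemar test uses discordant pairs only and matches stats::mcnemar.test", {
  res <- mcnemar_test(new_paired_table(0, 15, 5, 0))
  expect_equal(res$statistic, 5)
  expect_equal(res$p_value, 0.02534732, tolerance = 1e-6)
  # invariant to concordant counts
  res2 <- mcnemar_test(new_paired_table(99, 15, 5, 42))
  expect_equal(res2$statistic, res$statistic)
  # symmetric discordance: no signal
  expect_equal(mcnemar_test(new_paired_table(1, 10, 10, 1)),
    list(statistic = 0, p_value = 1))
  # no discordant pairs at all: conservative p = 1
  expect_equal(mcnemar_test(new_paired_table(5, 0, 0, 5)),
    list(statistic = 0, p_value = 1))
  # independent route: stats::mcnemar.test without correction
  tab <- matrix(c(7, 15, 5, 73), 2, 2)
  ref <- stats::mcnemar.test(tab, correct = FALSE)
  got <- mcnemar_test(new_paired_table(7, 15, 5, 73))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  # normal-approximation equivalence: statistic is ((b-c)/sqrt(b+c))^2
  set.seed(42)
  for (t in random_paired_tables(50)) {
    if (t$b + t$c == 0) next
    expect_equal(
      mcnemar_test(t)$statistic,
      ((t$b - t$c) / sqrt(t$b + t$c))^2
    )
  }
})

test_that("Pearson test equals the 2x2 chi-squared on the matched subjects", {
  # treated events 10/30, control events 20/30
  t <- new_paired_table(5, 5, 15, 5)
  res <- pearson_test(t)
  expect_equal(res$statistic, 6.6666667, tolerance = 1e-7)
  expect_equal(res$p_value, 0.009823275, tolerance = 1e-7)
  # equal proportions: no signal
  expect_equal(pearson_test(new_paired_table(5, 10, 10, 5)),
    list(statistic = 0, p_value = 1))
  # zero margin (no events anywhere): conservative p = 1
  expect_equal(pearson_test(new_paired_table(0, 0, 0, 10)),
    list(statistic = 0, p_value = 1))
  set.seed(43)
  for (t in random_paired_tables(50)) {
    n <- t$n
    tab <- matrix(
      c(t$a + t$b, n - t$a - t$b, t$a + t$c, n - t$a - t$c),
      2, 2,
      byrow = TRUE
    )
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    # two independent routes: textbook shortcut and stats::chisq.test
    expect_equal(pearson_test(t)$statistic, pearson_2x2_shortcut(tab),
      tolerance = 1e-10
    )
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(pearson_test(t)$statistic, unname(ref$statistic))
  }
})

test_that("Wald intervals are symmetric with width 2 z se", {
  expect_equal(unname(wald_ci(0.1, 0.05)), c(0.002, 0.198))
  expect_equal(unname(wald_ci(0.3, 0)), c(0.3, 0.3))
  set.seed(44)
  for (i in 1:20) {
    rd <- runif(1, -1, 1)
    se <- runif(1, 0, 0.2)
    ci <- wald_ci(rd, se)
    expect_equal(unname(diff(ci)), 2 * 1.96 * se)
    expect_equal(unname(mean(ci)), rd)
  }
})

test_that("full inference bundles a single shared point estimate", {
  t <- new_paired_table(10, 20, 5, 65)
  inf <- rd_inference(t)
  expect_equal(inf$rd, 0.15)
  expect_equal(unname(mean(inf$ci_independent)), inf$rd)
  expect_equal(unname(mean(inf$ci_paired)), inf$rd)
  # positive within-pair association (ad > bc): paired interval narrower
  expect_gt(t$a * t$d, t$b * t$c)
  expect_lt(
    diff(inf$ci_paired),
    diff(inf$ci_independent)
  )
  expect_equal(inf$se_independent, sqrt(var_independent(t)))
  expect_equal(inf$se_paired, sqrt(var_paired(t)))
})
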