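test_that("yield table reproduces the cohort's marginal and cumulative yields", {
  yt <- yield_table(fixture_matrix())
  expect_equal(attr(yt, "overall_yield"), 27 / 72)
  expect_equal(yt$yield, c(21, 4, 2) / 72)
  expect_equal(yt$cum_count, c(21, 25, 27))
  expect_equal(yt$cum_yield, c(21, 25, 27) / 72)

  zero <- outcome_matrix(cohort(data.frame(patient_id = letters[1:4],
                                           diagnostic_level = 0)), k = 3)
  yz <- yield_table(zero)
  expect_equal(yz$yield, rep(0, 3))
  expect_equal(attr(yz, "overall_yield"), 0)

  # record order cannot matter
  sim <- simulate_cohort(300, probs = c(0.3, 0.1, 0.05, 0.55), seed = 5)
  shuffled <- cohort(as.data.frame(sim)[sample(nrow(sim)), ])
  expect_equal(yield_table(outcome_matrix(shuffled))$count,
               yield_table(outcome_matrix(sim))$count)
})

test_that("percent formatter rounds or truncates at the kept digit", {
  expect_equal(format_pct(27 / 72), "37.5%")
  expect_equal(format_pct(21 / 72, digits = 0), "29%")
  expect_equal(format_pct(2 / 72, digits = 0), "3%")
  # 5.555...% truncates to one decimal rather than rounding to 5.6%
  expect_equal(format_pct(4 / 72, digits = 1, truncate = TRUE), "5.5%")
  expect_equal(format_pct(4 / 72, digits = 1, truncate = FALSE), "5.6%")
  expect_equal(format_p(c(0.41421, 0.0006739, 0.05)),
               c("0.414", "<0.001", "0.050"))
})

test_that("Cochran's Q on the study cohort matches its closed-form value", {
  q <- cochran_q(fixture_matrix())
  # hand evaluation: Q = 2 * (3*(21^2+4^2+2^2) - 27^2) / (3*27 - 27) = 1308/54
  expect_equal(unname(q$statistic), 1308 / 54, tolerance = 1e-12)
  expect_equal(unname(q$parameter), 2)
  # for df = 2 the upper tail is exp(-Q/2)
  expect_equal(q$p.value, exp(-(1308 / 54) / 2), tolerance = 1e-12)
  expect_lt(q$p.value, 0.01)
})

test_that("Cochran's Q degenerates gracefully when no proband is discordant", {
  same <- cohort(data.frame(patient_id = c("a", "b"), diagnostic_level = 0))
  expect_warning(q <- cochran_q(outcome_matrix(same, k = 2)), "degenerate")
  expect_equal(unname(q$statistic), 0)
  expect_equal(q$p.value, 1)
})

test_that("McNemar on marginal indicators reproduces the pairwise statistics", {
  m <- fixture_matrix()
  t12 <- mcnemar_pair(m, 1, 2)
  expect_equal(unname(t12$estimate), c(21, 4))
  expect_equal(unname(t12$statistic), 289 / 25, tolerance = 1e-12)
  expect_equal(round(t12$p.value, 3), 0.001)

  t23 <- mcnemar_pair(m, 2, 3)
  expect_equal(unname(t23$estimate), c(4, 2))
  expect_equal(unname(t23$statistic), 2 / 3, tolerance = 1e-12)
  expect_equal(t23$p.value, 0.414, tolerance = 1e-3)

  t13 <- mcnemar_pair(m, 1, 3)
  expect_equal(unname(t13$statistic), 361 / 23, tolerance = 1e-12)
  expect_lt(t13$p.value, 0.001)

  expect_error(mcnemar_pair(m, 2, 2), "distinct")
})

test_that("McNemar agrees with the stats::mcnemar.test cross-check", {
  m <- fixture_matrix()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ours <- mcnemar_pair(m, pair[1], pair[2])
    ref <- stats::mcnemar.test(table(factor(m[, pair[1]], levels = 0:1),
                                     factor(m[, pair[2]], levels = 0:1)),
                               correct = FALSE)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value)
  }
})

test_that("McNemar p-values match chi-square tail mass by numerical integration", {
  set.seed(42)
  for (i in 1:20) {
    b <- sample(0:30, 1)
    c_ <- sample(0:30, 1)
    if (b + c_ == 0) c_ <- 1
    lv <- c(rep(1, b), rep(2, c_))
    co <- cohort(data.frame(patient_id = sprintf("p%02d", seq_along(lv)),
                            diagnostic_level = lv))
    res <- mcnemar_pair(outcome_matrix(co, k = 2), 1, 2)
    expect_equal(res$p.value,
                 chisq_tail_by_integration(unname(res$statistic), df = 1),
                 tolerance = 1e-8)
  }
})

test_that("degenerate and exact variants behave as documented", {
  none <- outcome_matrix(cohort(data.frame(patient_id = "a",
                                           diagnostic_level = 0)), k = 2)
  res0 <- mcnemar_pair(none, 1, 2)
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p.value, 1)

  ex <- mcnemar_pair(fixture_matrix(), 2, 3, exact = TRUE)
  # exact two-sided binomial: 2 * P(X <= 2 | n = 6, p = 1/2)
  expect_equal(ex$p.value, 2 * pbinom(2, 6, 0.5), tolerance = 1e-12)
})

test_that("Cochran's Q reduces to the uncorrected McNemar statistic at k = 2", {
  set.seed(7)
  for (i in 1:50) {
    m <- random_outcome_matrix(n = sample(5:40, 1), k = 2)
    q <- suppressWarnings(cochran_q(m))
    mc <- mcnemar_pair(m, 1, 2)
    expect_equal(unname(q$statistic), unname(mc$statistic), tolerance = 1e-10)
  }
})

test_that("pairwise comparisons are ordered, flagged, and consistent", {
  pw <- pairwise_mcnemar(fixture_matrix(), alpha = 0.05)
  expect_equal(nrow(pw), 3)
  expect_equal(pw[, c("tier_a", "tier_b")],
               data.frame(tier_a = c(1, 1, 2), tier_b = c(2, 3, 3)))
  expect_equal(pw$significant, c(TRUE, TRUE, FALSE))
  expect_equal(which.max(pw$p_value), 3)  # tiers 2 vs 3 least significant

  k2 <- pairwise_mcnemar(random_outcome_matrix(20, 2))
  expect_equal(nrow(k2), 1)
})

test_that("observed tier imbalance is extreme under within-row label permutation", {
  m <- fixture_matrix()
  q_obs <- unname(cochran_q(m)$statistic)
  # permuting tier labels within each diagnosed proband assigns each
  # diagnosis to a uniform random tier; Q depends only on the column counts
  set.seed(2021)
  n_perm <- 10000
  n_diag <- sum(rowSums(m))
  q_perm <- replicate(n_perm, {
    cols <- tabulate(sample.int(3, n_diag, replace = TRUE), nbins = 3)
    2 * (3 * sum(cols^2) - n_diag^2) / (3 * n_diag - n_diag)
  })
  expect_lt(mean(q_perm >= q_obs), 0.001)
})
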