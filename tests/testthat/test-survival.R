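test_that("KM estimator reproduces hand product-limit values", {
  all_cens <- km_curve(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  expect_equal(all_cens$survival[1L], 1)  # S(0) = 1

  # times 1 (event), 2 (censored), 3 (event):
  # S(1) = 2/3; at t = 3 the risk set is 1, so S(3) = 2/3 * (1 - 1/1) = 0
  km <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("log-rank matches the hand-computed O-E/V statistic", {
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                      rep(c("a", "b"), each = 3))
  expect_lt(lr0$chi2, 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-6)

  # independent arithmetic on a small worked table
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n_a <- sum(at_risk & group == "a")
    d <- sum(times == t & events == 1)
    d_a <- sum(times == t & events == 1 & group == "a")
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  lr <- logrank_test(times, events, group)
  expect_equal(lr$chi2, o_minus_e^2 / v, tolerance = 1e-8)
  expect_equal(lr$df, 1L)
})

test_that("Cox binary hazard ratio behaves at the boundaries", {
  # identical survival in both groups -> HR ~ 1
  times <- rep(c(1, 2, 3, 4, 7, 9), 2)
  events <- rep(c(1, 1, 0, 1, 1, 0), 2)
  grp <- rep(c(0, 1), each = 6)
  fit <- cox_binary_hr(times, events, grp)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_true(fit$ci[1L] <= fit$hr && fit$hr <= fit$ci[2L])

  # sign symmetry: swapping group codes inverts the HR
  flipped <- cox_binary_hr(times, events, 1 - grp)
  expect_equal(flipped$hr, 1 / fit$hr, tolerance = 1e-8)

  # a group with no events is flagged as non-convergent
  expect_warning(
    nc <- cox_binary_hr(c(1, 2, 3, 4), c(1, 1, 0, 0), c(0, 0, 1, 1)),
    "no events")
  expect_false(nc$converged)
})

test_that("Kruskal-Wallis and Dunn follow the rank arithmetic", {
  identical_groups <- kruskal_wallis(rep(c(1, 2, 3), 3),
                                     rep(c("a", "b", "c"), each = 3))
  expect_lt(identical_groups$H, 1e-10)
  expect_equal(identical_groups$p, 1, tolerance = 1e-6)

  # hand example with a tie
  values <- c(1, 2, 2, 4, 5, 7)
  group <- c("a", "a", "b", "b", "c", "c")
  rk <- rank(values)
  N <- 6
  H <- (12 / (N * (N + 1))) *
    sum(tapply(rk, group, function(r) length(r) * mean(r)^2)) -
    3 * (N + 1)
  ties <- table(rk)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  kw <- kruskal_wallis(values, group)
  expect_equal(kw$H, H, tolerance = 1e-10)

  dn <- dunn_posthoc(values, group)
  expect_equal(nrow(dn), 3L)
  expect_true(all(dn$p_adjusted >= dn$p - 1e-12))
})

test_that("Fisher exact p equals table enumeration", {
  tab <- matrix(c(1, 9, 9, 1), 2)
  # enumerate all tables with the observed margins
  p_obs <- dhyper(tab[1, 1], 10, 10, 10)
  p_enum <- sum(vapply(0:10, function(x) {
    px <- dhyper(x, 10, 10, 10)
    if (px <= p_obs + 1e-12) px else 0
  }, 0))
  expect_equal(fisher_2x2(tab), p_enum, tolerance = 1e-10)

  expect_equal(fisher_2x2(matrix(c(0, 0, 3, 5), 2)), 1)  # zero margin
  expect_equal(fisher_2x2(matrix(c(4, 4, 4, 4), 2)), 1)  # symmetric
})

test_that("chi-squared test uses the uncorrected Pearson formula", {
  prop <- matrix(c(10, 20, 30, 60), 2)  # proportional rows
  expect_lt(chi2_contingency(prop)$chi2, 1e-10)

  tab <- matrix(c(12, 5, 7, 15), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  res <- chi2_contingency(tab)
  expect_equal(res$chi2, chi2, tolerance = 1e-10)
  expect_equal(res$df, 1L)
  perm <- chi2_contingency(tab[2:1, 2:1])
  expect_equal(perm$chi2, res$chi2, tolerance = 1e-10)
})

test_that("percentages are rounded half away from zero", {
  expect_identical(percent_report(91, 494), 18L)
  expect_identical(percent_report(44, 53), 83L)
  expect_identical(percent_report(0, 10), 0L)
  expect_identical(percent_report(1, 8), 13L)    # 12.5 -> 13
  expect_identical(percent_report(-1, 8), -13L)  # -12.5 -> -13
  expect_error(percent_report(1, 0), "denominator")
})

test_that("compare_survival bundles KM, log-rank and the HR", {
  truth <- data.frame(sample_id = sprintf("S%d", 1:400),
                      cellular = rep(c("g0", "g1"), each = 200),
                      immune = "IM-", batch = "b1")
  clin <- generate_survival(truth, c(g0 = 0.02, g1 = 0.01),
                            censor_rate = 0.005, horizon_months = 240,
                            seed = 13, label = "cellular")
  res <- compare_survival(clin$rfs_time, clin$event, truth$cellular)
  expect_s3_class(res, "survival_result")
  expect_named(res$km, c("g0", "g1"))
  expect_true(all(vapply(res$km, function(k)
    all(diff(k$survival) <= 1e-12), NA)))
  expect_lt(res$hr$hr, 1)  # g1 has the lower hazard
  expect_lt(res$logrank$p, 0.05)
  expect_output(print(res), "HR")
})
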