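test_that("Kaplan-Meier matches the hand product-limit and empirical survival", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(attr(km, "median"), 2)  # first time S(t) <= 0.5

  all_cens <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  expect_true(is.na(attr(all_cens, "median")))

  set.seed(60)
  t0 <- round(rexp(40, 0.1), 1)
  km2 <- km_estimate(t0, rep(1, 40))
  emp <- vapply(km2$time, function(u) mean(t0 > u), numeric(1))
  expect_equal(km2$survival, emp)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "Negative")
})

test_that("log-rank test: identical groups, hand-worked table, design errors", {
  t0 <- c(1, 2, 3, 4, 5)
  e0 <- c(1, 0, 1, 1, 0)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("A", "B"), each = 5))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # 6-subject worked example (O, E, V computed by hand):
  # A: 1+, 3+, 5c ; B: 2+, 4+, 6+  =>  O_A = 2,
  # E_A = 3/6 + 2/5 + 2/4 + 1/3 = 1.7333..., V = 0.9622...
  lr <- logrank_test(c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 1, 1),
                     rep(c("A", "B"), each = 3))
  e_a <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3
  v <- 0.25 + (2 / 5) * (3 / 5) + 0.25 + (1 / 3) * (2 / 3)
  expect_equal(lr$per_group$observed, c(2, 3))
  expect_equal(lr$per_group$expected, c(e_a, 5 - e_a), tolerance = 1e-10)
  expect_equal(lr$chi2, (2 - e_a)^2 / v, tolerance = 1e-10)

  expect_error(logrank_test(t0, e0, rep("A", 5)), "2 groups")
})

test_that("log-rank p agrees with a permutation null at small n", {
  set.seed(61)
  n <- 20
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.8)
  grp <- rep(c("A", "B"), each = 10)
  time[grp == "B"] <- time[grp == "B"] * 1.6
  obs <- logrank_test(time, event, grp)
  perm <- replicate(2000, logrank_test(time, event, sample(grp))$chi2)
  p_perm <- mean(perm >= obs$chi2 - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.05)
})

test_that("Cox regression recovers a planted log hazard ratio", {
  set.seed(62)
  n <- 500
  z <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.8 * z))
  cens <- rexp(n, 0.02)
  fit <- cox_univariate(pmin(time, cens), as.numeric(time <= cens), z)
  expect_lt(abs(fit$beta - 0.8), 0.15)
  expect_true(fit$converged)
  expect_equal(fit$hr, exp(fit$beta))

  # rescaling the covariate rescales beta reciprocally
  fit10 <- cox_univariate(pmin(time, cens), as.numeric(time <= cens), 10 * z)
  expect_equal(fit10$beta, fit$beta / 10, tolerance = 1e-6)
})

test_that("Cox Wald test holds its nominal size under the null", {
  set.seed(63)
  rej <- vapply(1:100, function(i) {
    n <- 100
    z <- rnorm(n)
    time <- rexp(n, 0.1)
    event <- rbinom(n, 1, 0.8)
    cox_univariate(time, event, z)$wald_p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.11)
})

test_that("Cox input validation", {
  expect_error(cox_univariate(c(1, 2, 3), c(1, 1, 0), c(2, 2, 2)), "constant")
  expect_error(cox_univariate(c(1, 2, 3), c(1, 0, 0), c(1, 2, 3)), "2 events")
})

test_that("time-dependent AUC: null marker near 0.5, perfect marker exactly 1", {
  set.seed(64)
  n <- 400
  time <- rexp(n, 1 / 40); event <- rbinom(n, 1, 0.7)
  marker <- rnorm(n)  # independent of survival
  expect_lt(abs(time_dependent_auc(marker, time, event, 30)$auc - 0.5), 0.05)

  t2 <- rexp(100, 1 / 40)
  res <- time_dependent_auc(-t2, t2, rep(1, 100), median(t2))
  expect_equal(res$auc, 1)
})

test_that("without censoring the estimator reduces to the binary AUC", {
  set.seed(65)
  n <- 150
  time <- rexp(n, 1 / 30)
  marker <- -0.5 * time + rnorm(n)
  h <- quantile(time, 0.6)
  got <- time_dependent_auc(marker, time, rep(1, n), h)$auc
  # oracle: Mann-Whitney AUC for cases T <= h vs controls T > h
  case <- marker[time <= h]; ctrl <- marker[time > h]
  mw <- (sum(outer(case, ctrl, ">")) + 0.5 * sum(outer(case, ctrl, "=="))) /
    (length(case) * length(ctrl))
  expect_equal(got, mw, tolerance = 1e-10)
})

test_that("AUC horizon outside the informative range errors", {
  expect_error(time_dependent_auc(rnorm(20), rexp(20, 1), rep(1, 20), 1e6),
               "0 or 1")
})

test_that("correlation wrapper: identity, monotone transforms, hand example", {
  x <- c(1.2, 3.4, 2.2, 5.5, 4.1)
  expect_equal(correlate(x, x)$estimate, 1)
  expect_equal(correlate(x, exp(x))$estimate, 1)           # spearman
  expect_lt(correlate(x, exp(x), "pearson")$estimate, 1)
  # 5-point hand computation: d^2 sum = 4 -> rho = 1 - 24/120 = 0.8
  got <- correlate(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(got$estimate, 0.8)
  expect_error(correlate(x, rep(1, 5)), "constant")
  expect_error(correlate(x, 1:4), "equal length")
})

test_that("group comparison dispatches wilcoxon vs kruskal-wallis", {
  set.seed(66)
  v <- rnorm(60)
  g2 <- rep(c("a", "b"), 30)
  g3 <- rep(c("a", "b", "c"), 20)
  expect_equal(compare_groups(v, g2)$test, "wilcoxon")
  expect_equal(compare_groups(v, g3)$test, "kruskal-wallis")
  expect_equal(compare_groups(v, g2)$p_value,
               suppressWarnings(wilcox.test(v ~ g2)$p.value))
})
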