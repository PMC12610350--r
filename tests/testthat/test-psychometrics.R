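# Two frozen matrices whose agreement ICCs were computed with an
# independent reference implementation (estimates to 6 decimals, CI
# bounds to 2): the 6x2 case gives ICC(A,1) = 0.732303 [0.05, 0.96] and
# ICC(A,k) = 0.845467 [0.09, 0.98]; the 10x3 case gives
# ICC(A,1) = -0.067196 [-0.35, 0.43] and ICC(A,k) = -0.232888 [-3.52, 0.69].
frozen_6x2 <- matrix(c(10.6094, 11.5009, 6.0979, 10.2557, 9.9664, 11.7588,
                       7.92, 11.8811, 7.3956, 9.3675, 8.2939, 11.5556), 6, 2)
frozen_10x3 <- matrix(c(50.5282, 43.1257, 57.0276, 44.5526, 46.5734, 52.9236,
                        67.1332, 43.4898, 49.0884, 55.2047,
                        59.0179, 52.95, 49.6006, 59.7803, 47.1829, 53.3019,
                        46.7487, 54.9278, 43.2787, 55.946,
                        53.7401, 42.3289, 48.5211, 48.7638, 54.2585, 53.4466,
                        45.9021, 59.0318, 43.4042, 54.3452), 10, 3)

test_that("agreement ICCs reproduce the frozen reference values", {
  r1 <- icc_agreement(frozen_6x2, "single")
  expect_equal(r1$estimate, 0.732303, tolerance = 1e-5)
  expect_equal(round(c(r1$lower, r1$upper), 2), c(0.05, 0.96))
  rk <- icc_agreement(frozen_6x2, "average")
  expect_equal(rk$estimate, 0.845467, tolerance = 1e-5)
  expect_equal(round(c(rk$lower, rk$upper), 2), c(0.09, 0.98))

  r2 <- icc_agreement(frozen_10x3, "single")
  expect_equal(r2$estimate, -0.067196, tolerance = 1e-5)
  expect_equal(round(c(r2$lower, r2$upper), 2), c(-0.35, 0.43))
  r2k <- icc_agreement(frozen_10x3, "average")
  expect_equal(r2k$estimate, -0.232888, tolerance = 1e-5)
  expect_equal(round(c(r2k$lower, r2k$upper), 2), c(-3.52, 0.69))
})

test_that("ICC degenerate and shifted cases behave as the model dictates", {
  # two identical columns: perfect agreement
  x <- c(3, 7, 2, 9, 5, 6)
  expect_equal(icc_agreement(cbind(x, x), "single")$estimate, 1)

  # adding a common constant to every cell changes nothing
  base <- icc_agreement(frozen_6x2, "single")$estimate
  expect_equal(icc_agreement(frozen_6x2 + 100, "single")$estimate, base)

  # a constant added to one column only: agreement drops far below the
  # consistency ICC of the same matrix
  shifted <- cbind(x, x + 50)
  agr <- icc_agreement(shifted, "single")$estimate
  cons <- oracle_icc_consistency(shifted)
  expect_equal(cons, 1, tolerance = 1e-12)
  expect_lt(agr, 0.2)

  # insufficient data and zero variance are explicit errors
  expect_error(icc_agreement(matrix(1:4, 2, 2)), "insufficient")
  expect_error(icc_agreement(matrix(rnorm(5), 5, 1)), "insufficient")
  expect_error(icc_agreement(matrix(3, 5, 2)), "zero total variance")

  # rows with missing trials are dropped and counted
  withna <- rbind(frozen_6x2, c(NA, 4))
  r <- icc_agreement(withna, "single")
  expect_equal(r$n_dropped, 1L)
  expect_equal(r$estimate, icc_agreement(frozen_6x2, "single")$estimate)
})

test_that("ICC and CI match the aov-based oracle on random matrices", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    M <- matrix(rnorm(n * k, 20, 4), n, k) +
      outer(rnorm(n, 0, 2), rep(1, k))
    for (form in c("single", "average")) {
      mine <- icc_agreement(M, form)
      orac <- oracle_icc(M, form)
      expect_equal(mine$estimate, orac$estimate, tolerance = 1e-8)
      expect_equal(mine$lower, orac$lower, tolerance = 1e-8)
      expect_equal(mine$upper, orac$upper, tolerance = 1e-8)
    }
  }
})

test_that("ICC labels follow the reliability thresholds", {
  expect_equal(classify_icc(0.31), "poor")
  expect_equal(classify_icc(0.82), "good")
  expect_equal(classify_icc(0.95), "excellent")
  expect_equal(classify_icc(c(0.49, 0.5, 0.749, 0.75, 0.899, 0.9)),
               c("poor", "moderate", "moderate", "good", "good", "excellent"))
})

test_that("the normality gate routes to the right omnibus test", {
  set.seed(88)
  # normal draws: all three independent per-column gates pass with
  # probability 0.95^3 = 0.857; check the empirical rate against that
  picks <- replicate(200, {
    choose_omnibus(matrix(rnorm(24 * 3, 10, 2), 24, 3))$test
  })
  expect_lt(abs(mean(picks == "rm_anova") - 0.95^3), 0.06)

  # one heavily skewed column triggers Friedman
  M <- matrix(rnorm(24 * 3, 10, 2), 24, 3)
  M[, 2] <- exp(M[, 2] / 2)
  expect_equal(choose_omnibus(M)$test, "friedman")

  # a constant column is degenerate, treated as non-normal
  M2 <- matrix(rnorm(24 * 3, 10, 2), 24, 3)
  M2[, 1] <- 7
  ch <- choose_omnibus(M2)
  expect_equal(ch$test, "friedman")
  expect_true(is.na(ch$shapiro_p[1]))

  expect_error(choose_omnibus(matrix(rnorm(12), 4, 3)), "at least 5")
})

test_that("RM-ANOVA matches the aov oracle and handles degeneracy", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    m <- sample(3:4, 1)
    M <- matrix(rnorm(n * m, 50, 5), n, m) + outer(rnorm(n, 0, 3), rep(1, m))
    mine <- rm_anova(M)
    orac <- oracle_rm_anova(M)
    expect_equal(mine$statistic, orac$F, tolerance = 1e-10)
    expect_equal(mine$p, orac$p, tolerance = 1e-10)
    expect_equal(mine$effect_size, orac$etap2, tolerance = 1e-10)
  }

  # identical columns: F = 0, effect size 0
  x <- rnorm(8)
  r0 <- rm_anova(cbind(x, x, x))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect_size, 0)
  expect_true(r0$degenerate)

  # Mauchly statistic agrees with the stats implementation
  M <- matrix(rnorm(60, 0, 1), 20, 3)
  M[, 3] <- M[, 3] * 3  # break sphericity
  mt <- stats::mauchly.test(stats::lm(M ~ 1), X = ~1)
  mine <- rm_anova(M)
  expect_equal(mine$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  expect_equal(mine$mauchly_p, mt$p.value, tolerance = 1e-10)
  expect_true(mine$gg_epsilon <= 1 && mine$gg_epsilon >= 1 / (ncol(M) - 1))
  expect_true(mine$gg_p >= 0 && mine$gg_p <= 1)
})

test_that("RM-ANOVA type-I rate at the corrected level is nominal", {
  set.seed(111)
  alpha <- bonferroni_alpha(0.05, 12)$alpha
  rejections <- sum(replicate(4000, {
    rm_anova(matrix(rnorm(24 * 3), 24, 3))$p < alpha
  }))
  # central 99.9% binomial band around the nominal rate
  band <- qbinom(c(5e-4, 1 - 5e-4), 4000, alpha)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})

test_that("Friedman chi-square and Kendall W match the rank-formula oracle", {
  set.seed(121)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    m <- sample(3:4, 1)
    M <- matrix(rnorm(n * m), n, m)
    mine <- friedman_rm(M)
    orac <- oracle_friedman(M)
    expect_equal(mine$statistic, orac$chisq, tolerance = 1e-10)
    expect_equal(mine$effect_size, orac$W, tolerance = 1e-10)
    expect_equal(mine$p, orac$p, tolerance = 1e-10)
  }

  # ties: hand-ranked 4x3 table with within-row ties
  M <- rbind(c(1, 1, 2), c(3, 1, 2), c(2, 2, 2), c(1, 3, 2))
  mine <- friedman_rm(M)
  orac <- oracle_friedman(M)
  expect_equal(mine$statistic, orac$chisq, tolerance = 1e-10)
  expect_equal(mine$effect_size, orac$W, tolerance = 1e-10)

  # perfectly concordant rankings: W = 1
  M <- t(replicate(8, c(1, 2, 3))) + matrix(rnorm(24, 0, 1e-6), 8, 3)
  expect_equal(friedman_rm(M)$effect_size, 1, tolerance = 1e-6)

  # fully tied rows: chi-square 0, W 0, p 1
  Mt <- matrix(5, 6, 3)
  rt <- friedman_rm(Mt)
  expect_equal(rt$statistic, 0)
  expect_equal(rt$effect_size, 0)
  expect_equal(rt$p, 1)
})

test_that("paired comparisons match the textbook computation", {
  set.seed(131)
  for (i in 1:20) {
    n <- sample(8:24, 1)
    x <- rnorm(n, 30, 5)
    y <- x + rnorm(n, 2, 3)
    mine <- paired_comparison(x, y, alpha = 0.004)
    orac <- oracle_paired_t(x, y)
    expect_equal(mine$t, orac$t, tolerance = 1e-10)
    expect_equal(mine$p, orac$p, tolerance = 1e-10)
    expect_equal(mine$ci, orac$ci, tolerance = 1e-10)
    expect_equal(mine$cohens_d, orac$dz, tolerance = 1e-10)
    expect_equal(sign(mine$t), sign(mine$mean_diff))
    expect_true(mine$ci[1] <= mine$mean_diff && mine$mean_diff <= mine$ci[2])
  }

  # identical conditions: t = 0, p = 1, flagged degenerate
  x <- rnorm(10)
  r0 <- paired_comparison(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)

  expect_error(paired_comparison(1:2, 2:3), "at least 3")
})

test_that("printed paired summaries reproduce their t statistics", {
  # cup-task duration contrast: mean diff -11.72 (SD 7.29), n = 23
  r <- paired_t_from_summary(-11.72, 7.29, 23)
  expect_equal(round(r$t, 2), -7.71)
  expect_equal(r$df, 22)
  # letter velocity: 38.22 (37.77), n = 24
  expect_equal(round(paired_t_from_summary(38.22, 37.77, 24)$t, 2), 4.96)
  # zero difference is exactly zero
  expect_equal(paired_t_from_summary(0, 3, 10)$t, 0)
  expect_error(paired_t_from_summary(1, 0, 10), "sd_diff")
})

test_that("Bonferroni correction divides the familywise level", {
  b <- bonferroni_alpha(0.05, 12)
  expect_equal(b$alpha, 0.05 / 12)
  expect_equal(b$reported, 0.004)
  expect_equal(bonferroni_alpha(0.05, 1)$alpha, 0.05)

  # the corrected level controls the familywise error rate under
  # independence: Monte-Carlo FWER stays at or below 0.05
  set.seed(141)
  fwer <- mean(replicate(3000, any(runif(12) < b$alpha)))
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 3000))
})
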