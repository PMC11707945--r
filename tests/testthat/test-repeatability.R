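test_that("Bland-Altman closed forms on textbook cases", {
  # zero-variance collapse
  ba0 <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ba0$bias, 1)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$loa_lower, 1)
  expect_equal(ba0$loa_upper, 1)

  # differences {-1, 0, 1}
  ba <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  # CI half-width: t(0.975, 2) * 1 * sqrt(1/3 + 1.96^2/4)
  half <- qt(0.975, 2) * sqrt(1 / 3 + 1.96^2 / 4)
  expect_equal(ba$loa_lower_ci, -1.96 + c(-1, 1) * half)
  expect_equal(ba$loa_upper_ci, 1.96 + c(-1, 1) * half)
  expect_equal(ba$pct_within_loa, 100)

  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman recovers generating moments on simulated data", {
  withr::local_seed(30)
  n <- 30
  mu <- 0.37
  sigma <- (1.73 - 0.37) / 1.96  # LOA approximately [-0.98, 1.73]
  d <- rnorm(n, mu, sigma)
  base <- rnorm(n, 15, 3)
  ba <- bland_altman(base + d, base)
  mc_err <- 3 * sigma / sqrt(n)
  expect_lt(abs(ba$bias - mu), mc_err)
  expect_lt(abs(ba$loa_upper - (mu + 1.96 * sigma)), 3 * mc_err)
  expect_lt(abs(ba$loa_lower - (mu - 1.96 * sigma)), 3 * mc_err)
})

test_that("Bland-Altman is antisymmetric in the graders", {
  withr::local_seed(4)
  x <- rnorm(20, 10, 2); y <- rnorm(20, 10, 2)
  ab <- bland_altman(x, y); ba <- bland_altman(y, x)
  expect_equal(ab$bias, -ba$bias)
  expect_equal(ab$loa_lower, -ba$loa_upper)
  expect_equal(ab$loa_upper, -ba$loa_lower)
})

test_that("two-way mean squares agree with the base-R linear-model ANOVA", {
  withr::local_seed(88)
  n <- 12
  x <- rnorm(n, 20, 4); y <- x + rnorm(n, 0.5, 1)
  ms <- gajunct:::two_way_mean_squares(x, y)
  df <- data.frame(value = c(x, y),
                   unit = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- anova(lm(value ~ unit + rater, data = df))
  expect_equal(ms$msr, tab["unit", "Mean Sq"])
  expect_equal(ms$msc, tab["rater", "Mean Sq"])
  expect_equal(ms$mse, tab["Residuals", "Mean Sq"])
})

test_that("ICC limits: perfect agreement, independent noise, variance ratio", {
  withr::local_seed(70)
  x <- rnorm(20, 10, 3)
  expect_equal(icc_agreement(x, x), 1)

  # zero unit variance, independent rater noise: ICC near 0
  n <- 500
  expect_lt(abs(icc_agreement(rnorm(n), rnorm(n))), 0.1)

  # unit SD 3, rater-error SD 1: ICC -> 9/10
  u <- rnorm(3000, 0, 3)
  icc <- icc_agreement(u + rnorm(3000), u + rnorm(3000))
  expect_lt(abs(icc - 0.9), 0.02)

  expect_warning(res <- icc_agreement(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(res))
})

test_that("ICC and CoR transform correctly under location/scale changes", {
  withr::local_seed(41)
  u <- rnorm(50, 0, 3)
  x <- u + rnorm(50); y <- u + rnorm(50)
  expect_equal(icc_agreement(x + 7, y + 7), icc_agreement(x, y))
  expect_equal(icc_agreement(3 * x, 3 * y), icc_agreement(x, y))
  c0 <- coefficient_of_repeatability(x, y)
  expect_equal(coefficient_of_repeatability(x + 7, y + 7)$cor_anova,
               c0$cor_anova)
  expect_equal(coefficient_of_repeatability(3 * x, 3 * y)$cor_anova,
               3 * c0$cor_anova)
})

test_that("CoR limits: identical graders give 0; known error SD gives 1.96*sqrt(2)", {
  x <- c(4, 8, 15, 16, 23)
  expect_equal(coefficient_of_repeatability(x, x)$cor_anova, 0)
  withr::local_seed(60)
  n <- 3000
  u <- rnorm(n, 0, 5)
  co <- coefficient_of_repeatability(u + rnorm(n), u + rnorm(n))
  expect_lt(abs(co$cor_anova - 1.96 * sqrt(2)) / (1.96 * sqrt(2)), 0.05)
  # for two raters the two conventions coincide algebraically
  expect_equal(co$cor_anova, co$cor_sd_diff, tolerance = 1e-9)
})

test_that("estimator error shrinks as the sample grows", {
  withr::local_seed(123)
  icc_true <- 9 / 10
  errs <- vapply(c(30, 300, 3000), function(n) {
    u <- rnorm(n, 0, 3)
    abs(icc_agreement(u + rnorm(n), u + rnorm(n)) - icc_true)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("repeated-measures Bland-Altman recovers variance components", {
  withr::local_seed(77)
  k <- 30; m <- 68
  sigma_a <- 20; sigma_e <- 30
  cl <- rep(seq_len(k), each = m)
  # average the estimates over replicates: the cluster-SD estimate from 30
  # clusters has ~13% sampling error per replicate
  est <- replicate(10, {
    a <- rnorm(k, 0, sigma_a)[cl]
    d <- -3 + a + rnorm(k * m, 0, sigma_e)
    base <- rnorm(k * m, 0, 150)
    rep_ba <- bland_altman_repeated(base + d, base, cl)
    c(sa = sqrt(rep_ba$sigma2_cluster), se = sqrt(rep_ba$sigma2_resid),
      width_ok = (rep_ba$loa_upper - rep_ba$loa_lower) /
        (2 * 1.96 * rep_ba$sd_total))
  })
  expect_lt(abs(mean(est["sa", ]) - sigma_a) / sigma_a, 0.15)
  expect_lt(abs(mean(est["se", ]) - sigma_e) / sigma_e, 0.15)
  expect_equal(unname(est["width_ok", ]), rep(1, 10))
})

test_that("repeated-measures variance components match lme4 REML on balanced data", {
  skip_if_not_installed("lme4")
  withr::local_seed(19)
  k <- 12; m <- 10
  cl <- rep(seq_len(k), each = m)
  d <- 1 + rnorm(k, 0, 4)[cl] + rnorm(k * m, 0, 2)
  rep_ba <- bland_altman_repeated(d, rep(0, length(d)), cl)
  fit <- lme4::lmer(d ~ 1 + (1 | cl),
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(rep_ba$sigma2_cluster, vc$vcov[vc$grp == "cl"],
               tolerance = 1e-4)
  expect_equal(rep_ba$sigma2_resid, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-4)
})

test_that("repeated-measures degenerate limits match plain Bland-Altman", {
  withr::local_seed(31)
  # one observation per cluster: identical to the unclustered analysis
  x <- rnorm(15); y <- rnorm(15)
  r1 <- bland_altman_repeated(x, y, seq_len(15))
  b1 <- bland_altman(x, y)
  expect_s3_class(r1, "bland_altman")
  expect_equal(r1$loa_lower, b1$loa_lower)

  # single cluster: falls back with a warning
  expect_warning(r2 <- bland_altman_repeated(x, y, rep(1, 15)),
                 "single cluster")
  expect_equal(r2$bias, b1$bias)

  # all differences equal: limits collapse to the common value
  base <- rnorm(20)
  r3 <- bland_altman_repeated(base + 2, base, rep(1:4, each = 5))
  expect_equal(r3$loa_lower, 2)
  expect_equal(r3$loa_upper, 2)

  # no cluster variance: close to pooled Bland-Altman
  d <- rnorm(200)
  r4 <- bland_altman_repeated(d, rep(0, 200), rep(1:10, each = 20))
  b4 <- bland_altman(d, rep(0, 200))
  expect_equal(r4$bias, b4$bias, tolerance = 1e-9)
  expect_equal(r4$sd_total, b4$sd_diff, tolerance = 0.1)
})

test_that("the bundled report carries the battery and the ICC form label", {
  withr::local_seed(8)
  u <- rnorm(25, 10, 3)
  x <- u + rnorm(25, 0, 0.5); y <- u + rnorm(25, 0, 0.5)
  rep <- repeatability_report(x, y, units = "dB")
  expect_equal(rep$icc, icc_agreement(x, y))
  expect_equal(rep$bland_altman$bias, mean(x - y))
  expect_match(rep$icc_form, "absolute agreement")
  expect_output(print(rep), "CoR")
})
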