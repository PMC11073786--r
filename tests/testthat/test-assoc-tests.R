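# Core conversions and the three sex-combined tests.

test_that("beta/se, z and p conversions agree with quantile oracles", {
  expect_equal(z_from_beta_se(1, 0.5), 2)
  expect_equal(z_from_beta_se(0, 3), 0)
  expect_equal(z_from_beta_se(-3.184, 0.2404), -13.24459235, tolerance = 1e-8)
  expect_error(z_from_beta_se(1, 0), "positive")
  expect_error(z_from_beta_se(1, -0.1), "positive")

  expect_equal(p_from_z(0), list(p = 1, neglog10p = 0))
  expect_equal(p_from_z(1.959964)$p, 0.05, tolerance = 1e-6)
  # far tail: matches a high-precision normal-tail computation and the
  # printed female p of the strongest urate SNP
  tail <- p_from_z(16.173)
  expect_equal(tail$p, 7.819606165e-59, tolerance = 1e-8)
  expect_equal(tail$neglog10p, 58.10681512, tolerance = 1e-8)

  expect_equal(z_from_p_sign(1, 1), 0)
  expect_equal(z_from_p_sign(2.24e-12, 1), 7.01866383, tolerance = 1e-7)
  expect_equal(z_from_p_sign(2.24e-12, -1), -7.01866383, tolerance = 1e-7)
  expect_error(z_from_p_sign(0, 1), "\\(0, 1\\]")
  expect_error(z_from_p_sign(1.5, 1), "\\(0, 1\\]")

  expect_equal(se_from_beta_p(2.0, 0.0455), 1.0, tolerance = 1e-5)
  expect_equal(se_from_beta_p(-3.837, 7.88e-59), 0.2372542, tolerance = 1e-6)
  expect_equal(se_from_beta_p(2.285, 1.44e-15), 0.2862697, tolerance = 1e-6)
  expect_error(se_from_beta_p(0, 0.5), "nonzero")
  expect_error(se_from_beta_p(1, 1), "\\(0, 1\\)")
})

test_that("z <-> p round trip is exact across the usable range", {
  z <- seq(-40, 40, by = 0.5)
  pp <- p_from_z(z)
  direct <- z_from_p_sign(pmax(pp$p, 1e-300), sign(z))
  ok <- pp$p > 1e-300
  expect_equal(direct[ok], z[ok], tolerance = 1e-6)
  expect_true(all(is.finite(pp$neglog10p)))
  expect_true(all(pp$neglog10p >= 0))
})

test_that("effect-difference test behaves as an interaction-only test", {
  null <- test_diff(0.4, 0.1, 0.4, 0.2)
  expect_equal(null$z, 0)
  expect_equal(null$p, 1)
  expect_error(test_diff(1, 0, 0, 1), "positive")

  # size under equal true effects, Monte-Carlo oracle
  set.seed(TEST_SEED)
  n <- 20000
  bF <- rnorm(n, 1, 1)
  bM <- rnorm(n, 1, 1)
  rej <- mean(test_diff(bF, 1, bM, 1)$p < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("linear meta-analysis follows inverse-variance weighting", {
  r <- test_meta_linear(1.3, 0.2, 1.3, 0.2)
  expect_equal(r$z, sqrt(2) * 1.3, tolerance = 1e-12)
  # scale invariance of the weights
  a <- test_meta_linear(2.1, 0.11, -0.7, 0.34)
  b <- test_meta_linear(2.1, 0.11 * 7, -0.7, 0.34 * 7)
  expect_equal(a$z, b$z, tolerance = 1e-12)
  expect_error(test_meta_linear(1, -1, 1, 1), "positive")
})

test_that("omnibus quadratic test is sign-symmetric with chi2 df=2 tail", {
  expect_equal(test_meta_quadratic(0, 0), list(chi2 = 0, p = 1, neglog10p = 0))
  a <- test_meta_quadratic(2.3, -1.1)
  expect_identical(a, test_meta_quadratic(-2.3, 1.1))
  expect_identical(a$chi2, test_meta_quadratic(-1.1, 2.3)$chi2)
  # statistic dominates each per-sex statistic
  zf <- rnorm(200); zm <- rnorm(200)
  expect_true(all(test_meta_quadratic(zf, zm)$chi2 >=
                    pmax(zf^2, zm^2) - 1e-12))
})

test_that("closed-form df=2 survival matches the generic chi-square tail", {
  chi2 <- c(0, 10^seq(-3, log10(2000), length.out = 60))
  closed <- test_meta_quadratic(sqrt(chi2), 0)
  generic_log <- pchisq(chi2, df = 2, lower.tail = FALSE, log.p = TRUE)
  expect_equal(-closed$neglog10p * log(10), generic_log, tolerance = 1e-9)
})

test_that("equal-SE decomposition: z_metaL^2 + z_diff^2 = chi2_metaQ", {
  set.seed(TEST_SEED)
  for (i in 1:50) {
    se <- runif(1, 0.05, 2)
    bF <- rnorm(1); bM <- rnorm(1)
    zF <- bF / se; zM <- bM / se
    l <- test_meta_linear(zF, se, zM, se)
    d <- test_diff(bF, se, bM, se)
    q <- test_meta_quadratic(zF, zM)
    expect_equal(l$z^2 + d$z^2, q$chi2, tolerance = 1e-9)
  }
})

test_that("run_all_tests is vectorized, null-consistent and uniform under H0", {
  null_pair <- data.frame(beta_F = 0, se_F = 1, beta_M = 0, se_M = 1)
  r <- run_all_tests(null_pair)
  expect_equal(r$p_diff, 1)
  expect_equal(r$p_metaL, 1)
  expect_equal(r$p_metaQ, 1)

  empty <- run_all_tests(null_pair[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("p_diff", "p_metaL", "p_metaQ") %in% names(empty)))

  expect_error(
    run_all_tests(data.frame(variant = "rsX", beta_F = 1, se_F = 0,
                             beta_M = 1, se_M = 1)),
    "rsX")

  # p-values uniform under the null for all three tests
  set.seed(TEST_SEED)
  n <- 1e5
  sims <- data.frame(beta_F = rnorm(n), se_F = 1, beta_M = rnorm(n), se_M = 1)
  r <- run_all_tests(sims)
  expect_gt(stats::ks.test(r$p_diff, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(r$p_metaL, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(r$p_metaQ, "punif")$p.value, 0.01)
})

test_that("worked-example rows reproduce the printed sex-combined p-values", {
  ur <- worked_example("urate")
  row <- ur[ur$variant == "rs6814556", ]
  seF <- se_from_beta_p(row$beta_F, row$p_F)
  seM <- se_from_beta_p(row$beta_M, row$p_M)
  full <- run_all_tests(data.frame(beta_F = row$beta_F, se_F = seF,
                                   beta_M = row$beta_M, se_M = seM))
  expect_equal(full$neglog10_p_diff, -log10(row$p_diff), tolerance = 0.2)
  expect_equal(full$neglog10_p_metaL, -log10(row$p_metaL), tolerance = 0.2)
  expect_equal(full$neglog10_p_metaQ, -log10(row$p_metaQ), tolerance = 0.05)
})
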