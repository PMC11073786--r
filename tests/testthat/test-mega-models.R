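# Stratified OLS, heteroskedastic FGLS and the meta/mega equivalence.

test_that("stratified OLS recovers sex-specific effects", {
  sc <- scenario(n_F = 5000, n_M = 5000, maf = 0.3, beta_F = 0.3, beta_M = 0,
                 mu_F = 0, mu_M = 1, sigma_F = 1, sigma_M = 1)
  strat <- stratified_gwas(simulate_cohort(sc, seed = TEST_SEED))
  expect_lt(abs(strat$beta[strat$group == "female"] - 0.3),
            3 * strat$se[strat$group == "female"])
  expect_lt(abs(strat$beta[strat$group == "male"]),
            3 * strat$se[strat$group == "male"])
  expect_equal(strat$maf, c(0.3, 0.3), tolerance = 0.02)
})

test_that("stratified OLS is invariant to row permutation", {
  coh <- simulate_cohort(scenario(n_F = 300, n_M = 300, beta_F = 0.2),
                         seed = TEST_SEED)
  perm <- sample(length(coh$y))
  coh2 <- as_cohort(y = coh$y[perm], g = coh$g[perm], s = coh$s[perm])
  expect_equal(stratified_gwas(coh)[, -1], stratified_gwas(coh2)[, -1],
               tolerance = 1e-12)
})

test_that("degenerate designs are caught", {
  coh <- as_cohort(y = rnorm(100), g = rep(0:1, 50), s = rep(0:1, each = 50))
  coh$g[coh$s == 1] <- 1 # constant genotype among males
  expect_error(stratified_gwas(coh), "male")
  # noiseless phenotype: flagged, not silently wrong
  g <- c(rep(0:2, 20), rep(0:2, 20))
  coh2 <- as_cohort(y = 0.5 * g, g = g, s = rep(0:1, each = 60))
  # both strata are noiseless, so both warn
  expect_warning(expect_warning(res <- stratified_gwas(coh2), "degenerate"),
                 "degenerate")
  expect_equal(res$beta, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("fully stratified joint fit decouples into per-stratum OLS", {
  sc <- scenario(n_F = 800, n_M = 600, maf = 0.25, beta_F = 0.3,
                 beta_M = -0.15, mu_F = 1, mu_M = 3,
                 sigma_F = 1, sigma_M = 2,
                 covariates = list(age = list(effect = 0.02,
                                              sample = function(n) rnorm(n, 50, 8))))
  coh <- simulate_cohort(sc, seed = TEST_SEED)
  strat <- stratified_gwas(coh)
  fit <- fit_hetero_regression(coh, model = "joint",
                               covariate_mode = "fully_stratified")
  bF <- strat$beta[strat$group == "female"]
  bM <- strat$beta[strat$group == "male"]
  expect_equal(unname(fit$coefficients["g"]), bF, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["g:s"]), bM - bF, tolerance = 1e-8)
  expect_equal(sqrt(fit$vcov["g", "g"]), strat$se[strat$group == "female"],
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("FGLS recovers sex-specific residual variances", {
  sc <- scenario(n_F = 20000, n_M = 20000, maf = 0.3, beta_F = 0.1,
                 beta_M = 0.2, sigma_F = 1, sigma_M = 2)
  fit <- fit_hetero_regression(simulate_cohort(sc, seed = TEST_SEED),
                               model = "joint")
  # var(sigma2_hat) ~ 2 sigma^4 / n
  expect_lt(abs(fit$sigma2_F - 1), 3 * sqrt(2 / 20000))
  expect_lt(abs(fit$sigma2_M - 4), 3 * 4 * sqrt(2 / 20000))
})

test_that("homoskedastic data reduce FGLS to single-variance OLS", {
  coh <- simulate_cohort(scenario(n_F = 1000, n_M = 1000, beta_F = 0.2,
                                  beta_M = 0.2, mu_M = 0), seed = TEST_SEED)
  fit <- fit_hetero_regression(coh, model = "joint")
  D <- cbind(1, coh$g, coh$s, coh$g * coh$s)
  ols <- qr.solve(D, coh$y)
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-6)
})

test_that("2-df Wald equals the quadratic meta statistic in stratified mode", {
  for (i in 1:5) {
    sc <- scenario(n_F = 400, n_M = 500, beta_F = 0.3 * (i - 3),
                   beta_M = 0.1 * i, sigma_F = 1, sigma_M = 1.4)
    coh <- simulate_cohort(sc, seed = derive_seed(TEST_SEED, i))
    strat <- stratified_gwas(coh)
    meta <- test_meta_quadratic(strat$z[1], strat$z[2])
    fit <- fit_hetero_regression(coh, "joint", "fully_stratified")
    expect_equal(wald_joint_2df(fit)$chi2, meta$chi2, tolerance = 1e-6)
  }
})

test_that("Wald tests enforce the matching model and respect recoding", {
  coh <- simulate_cohort(scenario(n_F = 300, n_M = 300), seed = TEST_SEED)
  joint <- fit_hetero_regression(coh, "joint")
  main <- fit_hetero_regression(coh, "main_only")
  expect_error(wald_joint_2df(main), "joint")
  expect_error(wald_main_1df(joint), "main_only")

  # swapping the stratum labels reparameterizes g:s as g:(1-s); the 2-df
  # statistic is invariant (up to which stratum the variance df favours,
  # symmetric here)
  w_orig <- wald_joint_2df(joint)
  coh3 <- as_cohort(y = coh$y, g = coh$g, s = 1 - coh$s)
  w_swap <- wald_joint_2df(fit_hetero_regression(coh3, "joint"))
  expect_equal(w_swap$chi2, w_orig$chi2, tolerance = 1e-6)
})

test_that("1-df mega test tracks the linear meta-analysis under homogeneity", {
  sc <- scenario(n_F = 1000, n_M = 1000, beta_F = 0.1, beta_M = 0.1,
                 mu_F = 0, mu_M = 1)
  z_meta <- z_mega <- numeric(100)
  for (i in 1:100) {
    coh <- simulate_cohort(sc, seed = derive_seed(TEST_SEED, i))
    strat <- stratified_gwas(coh)
    z_meta[i] <- test_meta_linear(strat$z[1], strat$se[1],
                                  strat$z[2], strat$se[2])$z
    fit <- fit_hetero_regression(coh, "main_only")
    z_mega[i] <- wald_main_1df(fit)$z
  }
  expect_gt(cor(z_meta, z_mega), 0.999)
})

test_that("equivalence checker reports exact 2-df agreement and handles n=0", {
  sc <- scenario(n_F = 300, n_M = 300, beta_F = 0.2, beta_M = -0.2,
                 sigma_F = 1, sigma_M = 1.5)
  eq <- check_meta_mega_equivalence(sc, n_sims = 10, seed = TEST_SEED)
  expect_lt(eq$max_abs_diff_chi2, 1e-6)
  empty <- check_meta_mega_equivalence(sc, n_sims = 0, seed = TEST_SEED)
  expect_equal(nrow(empty$sims), 0)
  expect_true(is.na(empty$max_abs_diff_chi2))
})
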