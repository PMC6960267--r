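test_that("log_joint equals an independent term-by-term computation", {
  tr <- make_truth(3, 2, seed = 8)
  dat <- generate_dataset(tr, seed = 9)
  hyper <- list(sigma_theta_tau = 0.4, mu = c(-0.2, 2.9),
                Sigma_I = matrix(c(1.1, 0.2, 0.2, 0.3), 2, 2))
  for (mo in c("sathm", "rmhm", "m0", "rtonly")) {
    got <- log_joint(dat, tr$item, tr$zeta, tr$person, hyper, model = mo)
    want <- oracle_log_joint(dat, tr$item, tr$zeta, tr$person, hyper, mo)
    expect_equal(got, want, tolerance = 1e-10, info = mo)
  }
})

test_that("log_joint returns -Inf out of support and reacts to sigma misfit", {
  tr <- make_truth(4, 3, seed = 12)
  dat <- generate_dataset(tr, seed = 13)
  hyper <- list(sigma_theta_tau = 0.5, mu = c(0, 3), Sigma_I = diag(2))
  bad <- tr$item; bad$a[1] <- -0.5
  expect_identical(log_joint(dat, bad, tr$zeta, tr$person, hyper, "sathm"), -Inf)
  hyper_bad <- hyper; hyper_bad$sigma_theta_tau <- 1.5
  expect_identical(log_joint(dat, tr$item, tr$zeta, tr$person, hyper_bad, "sathm"), -Inf)
  # inflating residual SDs far above the data scale lowers the joint density
  infl <- tr$item; infl$sigma <- infl$sigma * 50
  expect_lt(log_joint(dat, infl, tr$zeta, tr$person, hyper, "sathm"),
            log_joint(dat, tr$item, tr$zeta, tr$person, hyper, "sathm"))
})

test_that("compiled likelihood sums agree with the R reference likelihood", {
  tr <- make_truth(6, 5, seed = 31)
  dat <- generate_dataset(tr, seed = 32)
  dat$mask[2, 3] <- FALSE                      # exercise missingness
  hyper <- list(sigma_theta_tau = 0.5, mu = c(0, 3), Sigma_I = diag(2))
  for (mo in c("sathm", "rmhm", "m0")) {
    ll <- sathm:::loglik_sums_cpp(
      dat$responses, dat$log_times, sathm:::as_int_matrix(dat$mask),
      sathm:::model_code(mo), tr$person$theta, tr$person$tau, tr$item$a,
      tr$item$b, tr$item$beta, tr$item$sigma, tr$item$alpha, tr$zeta)
    want <- oracle_log_joint(dat, tr$item, tr$zeta, tr$person, hyper, mo) -
      oracle_log_joint(dat, tr$item, tr$zeta, tr$person, hyper, "rtonly") +
      (if (mo == "sathm") -dnorm(tr$zeta, log = TRUE) else 0) -
      (if (mo %in% c("sathm", "rmhm"))
         sum(log(2) + dnorm(tr$item$alpha, log = TRUE)) else 0)
    expect_equal(ll$resp, want, tolerance = 1e-9, info = mo)
  }
})

test_that("dic computes D_bar, p_D and their sum", {
  d <- dic(c(10, 12), 9)
  expect_identical(d$D_bar, 11)
  expect_identical(d$p_D, 2)
  expect_identical(d$DIC, 13)
  d2 <- dic(rep(42.5, 20), 42.5)
  expect_equal(d2$p_D, 0)
  expect_equal(d2$DIC, 42.5)
  set.seed(1)
  dd <- rnorm(100, 500, 5)
  d3 <- dic(dd, 490)
  expect_equal(d3$DIC, 2 * mean(dd) - 490)
  expect_error(dic(c(1, NaN), 1), "finite")
  expect_error(dic(numeric(0), 1), "empty")
})

test_that("psrf is ~1 for identical chains, small for iid chains, large for separated ones", {
  set.seed(4)
  n <- 5000
  x <- matrix(rnorm(2 * n), ncol = 2)
  # identical chains: no between-chain variance, R-hat = (n-1)/n exactly
  expect_equal(psrf(list(x, x)), (n - 1) / n, tolerance = 1e-12)
  expect_lt(abs(psrf(list(x, x)) - 1), 1e-3)
  # two chains from the same distribution
  y <- matrix(rnorm(2 * n), ncol = 2)
  expect_lt(psrf(list(x, y)), 1.05)
  # separated chains force a large between-chain term
  expect_gt(psrf(list(x[, 1], x[, 1] + 10)), 5)
  expect_error(psrf(list(x)), "2 chains")
  expect_error(psrf(list(x[1:5, ], y[1:5, ])), "10 draws")
})

test_that("retained-draw bookkeeping follows n_iter, burn_in and thin", {
  tr <- make_truth(6, 3, seed = 41)
  dat <- generate_dataset(tr, seed = 42)
  cfg <- mcmc_config(n_iter = 102, burn_in = 100, thin = 2, seed = 1)
  fit <- run_mcmc(dat, "sathm", cfg)
  expect_equal(nrow(fit$draws[[1]]), 1)        # ceil(2/2)
  cfg3 <- mcmc_config(n_iter = 105, burn_in = 100, thin = 2, seed = 1)
  expect_equal(nrow(run_mcmc(dat, "sathm", cfg3)$draws[[1]]), 3)  # ceil(5/2)
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("chains are exactly reproducible and respect parameter supports", {
  tr <- make_truth(25, 6, seed = 51)
  dat <- generate_dataset(tr, seed = 52)
  cfg <- short_config(seed = 7)
  f1 <- run_mcmc(dat, "sathm", cfg)
  f2 <- run_mcmc(dat, "sathm", cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$dic, f2$dic)

  pooled <- do.call(rbind, f1$draws)
  expect_true(all(pooled[, grep("^a\\[", colnames(pooled))] > 0))
  expect_true(all(pooled[, grep("^sigma\\[", colnames(pooled))] > 0))
  expect_true(all(pooled[, grep("^alpha\\[", colnames(pooled))] > 0))
  expect_true(all(abs(pooled[, "rho"]) < 1))
  expect_true(all(pooled[, "sigma_b2"] > 0 & pooled[, "sigma_beta2"] > 0))
  expect_true(all(pooled[, "sigma_b2"] * pooled[, "sigma_beta2"] -
                    pooled[, "sigma_bbeta"]^2 > 0))
  # DIC identity holds for the reported values
  expect_equal(f1$dic$DIC, f1$dic$D_bar + f1$dic$p_D)
  # credible intervals bracket the posterior means
  expect_true(all(f1$summary$lower <= f1$summary$mean + 1e-12))
  expect_true(all(f1$summary$mean <= f1$summary$upper + 1e-12))
})

test_that("with the response likelihood disabled, time intensities match normal theory", {
  # RT-only fit: centered posterior means of beta should match the centered
  # column means of log time (the closed-form estimate under a flat level)
  tr <- make_truth(200, 8, seed = 61)
  dat <- generate_dataset(tr, seed = 62)
  fit <- run_mcmc(dat, "rtonly", mcmc_config(n_iter = 1500, burn_in = 500, seed = 3))
  bhat <- posterior_means(fit, "beta")
  closed <- colMeans(dat$log_times)
  expect_equal(bhat - mean(bhat), closed - mean(closed), tolerance = 0.03)
  # and residual SDs match the column SDs of the residual log times
  resid_sd <- apply(dat$log_times + tr$person$tau, 2, sd)
  expect_equal(posterior_means(fit, "sigma"), resid_sd, tolerance = 0.15)
})

test_that("credible intervals for the ability-speed correlation cover the truth", {
  hits <- 0
  for (r in 1:6) {
    tr <- make_truth(150, 12, seed = 70 + r, model = "m0")
    dat <- generate_dataset(tr, seed = 170 + r)
    fit <- run_mcmc(dat, "m0", mcmc_config(n_iter = 1200, burn_in = 400,
                                           seed = 70 + r))
    s <- fit$summary[fit$summary$parameter == "rho", ]
    hits <- hits + (s$lower <= 0.5 && 0.5 <= s$upper)
  }
  expect_gte(hits, 5)
})
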