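test_that("two_pl matches closed-form values and logistic symmetry", {
  expect_equal(two_pl(0, 1, 0), 0.5)
  expect_equal(two_pl(1, 2, 1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  # midpoint: theta = b/a gives 0.5 for any positive a
  for (a in c(0.3, 1, 2.7)) for (b in c(-2, 0, 1.5))
    expect_equal(two_pl(b / a, a, b), 0.5)
  # symmetry: P(-theta; a, -b) + P(theta; a, b) = 1
  th <- seq(-3, 3, length.out = 13)
  expect_equal(two_pl(-th, 1.3, -0.7) + two_pl(th, 1.3, 0.7), rep(1, 13))
  # numerically stable for extreme linear predictors
  expect_true(is.finite(two_pl(50, 50, -50)))
  expect_true(two_pl(50, 50, -50) <= 1 && two_pl(-50, 50, 50) >= 0)
  expect_error(two_pl(0, -1, 0), "a")
  expect_error(two_pl(NA, 1, 0))
  expect_error(two_pl(Inf, 1, 0))
})

test_that("residual_z standardizes log response times", {
  expect_equal(residual_z(3 - 0.5, 3, 0.5, 0.7), 0)
  expect_equal(residual_z(3 - 0.5 + 0.7, 3, 0.5, 0.7), 1)
  expect_equal(residual_z(2.0, 3.0, 0.5, 0.5), -1.0)
  expect_error(residual_z(1, 1, 0, 0), "sigma")
  expect_error(residual_z(1, 1, 0, -1), "sigma")
})

test_that("satm_prob is the 2PL asymptote attenuated by the time term", {
  expect_equal(satm_prob(0, 1, 0, 0.5, 0, 0), 0.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  # sufficient time: reduces to the 2PL asymptote
  expect_equal(satm_prob(0.7, 1.2, 0.3, 1, 10, 2.6431),
               two_pl(0.7, 1.2, 0.3), tolerance = 1e-15)
  # zero slope kills the z-dependence
  z <- seq(-4, 4, length.out = 9)
  p0 <- satm_prob(0.2, 1, 0.1, 0, z, 0)
  expect_equal(p0, rep(two_pl(0.2, 1, 0.1) * (1 - exp(-1)), 9))
  expect_error(satm_prob(0, 1, 0, 1, Inf, 0))
})

test_that("rmm_prob matches closed forms and reduces to 2PL at alpha = 0", {
  expect_equal(rmm_prob(0, 1, 0, 1, 0), 0.5)
  expect_equal(rmm_prob(0, 1, 0, 1, 3), 1 / (1 + exp(-3)), tolerance = 1e-12)
  z <- seq(-5, 5, length.out = 11)
  expect_equal(rmm_prob(0.4, 1.1, -0.2, 0, z),
               rep(two_pl(0.4, 1.1, -0.2), 11))
})

test_that("SATM stays below its asymptote while RMM approaches 1", {
  # contrast between the two response models: for any ability, the
  # speed-accuracy tradeoff probability is bounded by the 2PL asymptote,
  # the moderation probability is not
  th <- seq(-2, 2, length.out = 5); z <- seq(-3, 6, length.out = 25)
  for (t in th) {
    lam <- two_pl(t, 0.9, 0.4)
    ps <- satm_prob(t, 0.9, 0.4, 0.8, z, 0.2)
    pr <- rmm_prob(t, 0.9, 0.4, 0.8, z)
    expect_true(all(ps > 0 & ps <= lam))
    # strictly below away from the saturated regime
    zs <- z[z < 2]
    expect_true(all(satm_prob(t, 0.9, 0.4, 0.8, zs, 0.2) < lam))
    expect_true(max(pr) > lam)        # exceeds the asymptote for large z
  }
  expect_gt(rmm_prob(-2, 0.9, 2, 1, 40), 0.999999)
})

test_that("satm_prob and rmm_prob are monotone in z with the sign of alpha", {
  z <- seq(-6, 6, length.out = 61)
  for (al in c(0.5, 1.5)) {
    expect_true(all(diff(satm_prob(0.3, 1, 0, al, z, 0.1)) >= 0))
    expect_true(all(diff(rmm_prob(0.3, 1, 0, al, z)) >= 0))
    expect_true(all(diff(satm_prob(0.3, 1, 0, -al, z, 0.1)) <= 0))
    expect_true(all(diff(rmm_prob(0.3, 1, 0, -al, z)) <= 0))
  }
})

test_that("lognormal RT density normalizes, peaks at beta - tau, matches closed form", {
  beta <- 1.2; tau <- 0.3; sigma <- 0.7
  f <- function(t) exp(lognormal_rt_logpdf(t, beta, tau, sigma))
  expect_equal(stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # density in ln T peaks at beta - tau
  lt <- seq(-2, 4, length.out = 601)
  dens_ln <- lognormal_rt_logpdf(exp(lt), beta, tau, sigma) + lt
  expect_equal(lt[which.max(dens_ln)], beta - tau, tolerance = 0.01)
  expect_equal(lognormal_rt_logpdf(exp(1), 1, 0, 1),
               -0.5 * log(2 * pi) - 1, tolerance = 1e-12)
  expect_error(lognormal_rt_logpdf(0, 1, 0, 1), "time")
  expect_error(lognormal_rt_logpdf(-1, 1, 0, 1), "time")
})

test_that("sat_curve follows the exponential approach to asymptote", {
  expect_equal(sat_curve(1, 1, 1, 0), 1 - exp(-1), tolerance = 1e-12)
  # one time-constant above the intercept
  for (lam in c(0.5, 0.9)) for (phi in c(0.5, 2)) for (delta in c(0, 0.4))
    expect_equal(sat_curve(delta + 1 / phi, lam, phi, delta),
                 lam * (1 - exp(-1)), tolerance = 1e-12)
  t <- seq(0.5, 8, length.out = 40)
  d <- sat_curve(t, 0.8, 1.5, 0.3)
  expect_true(all(diff(d) > 0))
  expect_equal(sat_curve(1e6, 0.8, 1.5, 0.3), 0.8, tolerance = 1e-12)
  expect_error(sat_curve(0.2, 0.8, 1.5, 0.3), "delta")
})

test_that("fit_sat_curve recovers noiseless parameters and flags degeneracy", {
  t <- seq(0.5, 4, length.out = 8)
  fit <- fit_sat_curve(t, sat_curve(t, 0.9, 2, 0.3))
  expect_true(fit$converged)
  expect_equal(fit$lam, 0.9, tolerance = 1e-4)
  expect_equal(fit$phi, 2, tolerance = 1e-3)
  expect_equal(fit$delta, 0.3, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)

  flat <- fit_sat_curve(t, rep(0.7, 8))
  expect_true(flat$degenerate)
  expect_false(flat$converged)

  expect_error(fit_sat_curve(t[1:3], c(0.1, 0.2, 0.3)), "4")
  expect_error(fit_sat_curve(rev(t), sat_curve(t, 0.9, 2, 0.3)), "increasing")
})

test_that("fit_sat_curve recovers the asymptote under measurement noise", {
  t <- seq(0.4, 5, length.out = 10)
  truth <- sat_curve(t, 1, 1, 0)
  set.seed(99)
  lams <- replicate(100, {
    acc <- pmin(pmax(truth + rnorm(10, 0, 0.01), 0), 1)
    fit_sat_curve(t, acc)$lam
  })
  expect_true(all(abs(lams - 1) <= 0.05))
})
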