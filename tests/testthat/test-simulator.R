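test_that("item draws respect supports, dimensions and the generating means", {
  des <- sim_design(n_items = 30, seed = 5)
  set.seed(5)
  it <- draw_items(des)
  expect_equal(nrow(it$item), 30)
  expect_true(all(it$item$a > 0))
  expect_true(all(it$item$sigma > 0))
  expect_true(all(it$item$alpha > 0))

  # Monte-Carlo check of generating means over many items:
  # b ~ mean 0 (sd 1), beta ~ mean 3 (sd 0.5), a half-normal mean sqrt(2/pi)
  des2 <- sim_design(n_items = 10000, seed = 11)
  set.seed(11)
  big <- draw_items(des2)$item
  expect_lt(abs(mean(big$b) - 0), 3 * 1 / sqrt(10000))
  expect_lt(abs(mean(big$beta) - 3), 3 * 0.5 / sqrt(10000))
  expect_lt(abs(mean(big$a) - sqrt(2 / pi)), 3 * 0.61 / sqrt(10000))
  expect_lt(abs(mean(1 / big$sigma) - sqrt(2 / pi)), 3 * 0.61 / sqrt(10000))
  # item-level correlation of (b, beta): 0.25 / sqrt(0.25) = 0.5
  expect_lt(abs(cor(big$b, big$beta) - 0.5), 0.03)
})

test_that("person draws satisfy the identification constraints and correlation", {
  des <- sim_design(n_persons = 100000, seed = 3)
  set.seed(3)
  pe <- draw_persons(des)
  expect_lt(abs(cor(pe$theta, pe$tau) - 0.5), 0.01)
  expect_lt(abs(var(pe$theta) - 1), 0.02)
  expect_lt(abs(var(pe$tau) - 1), 0.02)
  expect_lt(abs(mean(pe$theta)), 0.012)
})

test_that("draws are bit-identical under a fixed seed", {
  des <- sim_design(n_persons = 50, n_items = 20, seed = 9)
  t1 <- draw_truth(des); t2 <- draw_truth(des)
  expect_identical(t1, t2)
  d1 <- generate_dataset(t1); d2 <- generate_dataset(t2)
  expect_identical(d1, d2)
})

test_that("generated residual log-times are standardized by construction", {
  des <- sim_design(n_persons = 500, n_items = 30, seed = 21)
  tr <- draw_truth(des)
  dat <- generate_dataset(tr)
  z <- (dat$log_times - outer(-tr$person$tau, tr$item$beta, `+`)) /
    matrix(tr$item$sigma, 500, 30, byrow = TRUE)
  expect_lt(abs(mean(z)), 0.02)
  expect_equal(var(as.numeric(z)), 1, tolerance = 0.02)
})

test_that("M0 generation matches the 2PL cell probabilities", {
  des <- sim_design(n_persons = 2000, n_items = 10, generating_model = "m0",
                    seed = 13)
  tr <- draw_truth(des)
  dat <- generate_dataset(tr)
  for (j in 1:10) {
    pbar <- mean(two_pl(tr$person$theta, tr$item$a[j], tr$item$b[j]))
    se <- sqrt(pbar * (1 - pbar) / 2000)
    expect_lt(abs(mean(dat$responses[, j]) - pbar), 4 * se + 0.01)
  }
})

test_that("a strong positive residual-time slope makes slow responses more accurate", {
  tr <- make_truth(2000, 8, seed = 17, alpha = 2, zeta = 0)
  dat <- generate_dataset(tr, seed = 18)
  z <- (dat$log_times - outer(-tr$person$tau, tr$item$beta, `+`)) /
    matrix(tr$item$sigma, 2000, 8, byrow = TRUE)
  for (j in 1:8) {
    qs <- quantile(z[, j], c(0.25, 0.75))
    acc_fast <- mean(dat$responses[z[, j] <= qs[1], j])
    acc_slow <- mean(dat$responses[z[, j] >= qs[2], j])
    expect_gt(acc_slow, acc_fast)
  }
})

test_that("tradeoff generation attenuates accuracy below the 2PL asymptote", {
  des <- sim_design(n_persons = 3000, n_items = 12, seed = 29)
  tr <- draw_truth(des)
  dat <- generate_dataset(tr)
  for (j in 1:12) {
    asym <- mean(two_pl(tr$person$theta, tr$item$a[j], tr$item$b[j]))
    expect_lt(mean(dat$responses[, j]), asym)
  }
})

test_that("design validation rejects invalid covariance and correlation", {
  expect_error(sim_design(item_cov = matrix(c(1, 2, 2, 1), 2, 2)), "definite")
  expect_error(sim_design(sigma_theta_tau = 1.2))
})
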