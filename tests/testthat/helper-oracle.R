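# term-by-term oracle for the unnormalized log posterior, written as explicit
# scalar loops independent of the vectorized implementation
oracle_log_joint <- function(dat, item, zeta, person, hyper, model) {
  N <- nrow(dat$responses); J <- ncol(dat$responses)
  ll <- 0
  for (i in seq_len(N)) for (j in seq_len(J)) {
    if (!dat$mask[i, j]) next
    lt <- dat$log_times[i, j]
    z <- (lt - (item$beta[j] - person$tau[i])) / item$sigma[j]
    ll <- ll + dnorm(lt, item$beta[j] - person$tau[i], item$sigma[j], log = TRUE) - lt
    if (model != "rtonly") {
      lam <- plogis(item$a[j] * person$theta[i] - item$b[j])
      p <- switch(model,
        sathm = lam * (1 - exp(-exp(item$alpha[j] * z + zeta))),
        rmhm = plogis(item$a[j] * person$theta[i] - item$b[j] + item$alpha[j] * z),
        m0 = lam)
      ll <- ll + if (dat$responses[i, j] == 1) log(p) else log(1 - p)
    }
  }
  r <- hyper$sigma_theta_tau
  for (i in seq_len(N)) {
    q <- (person$theta[i]^2 - 2 * r * person$theta[i] * person$tau[i] +
            person$tau[i]^2) / (1 - r^2)
    ll <- ll - log(2 * pi) - 0.5 * log(1 - r^2) - q / 2
  }
  S <- hyper$Sigma_I; Sinv <- solve(S)
  for (j in seq_len(J)) {
    x <- c(item$b[j] - hyper$mu[1], item$beta[j] - hyper$mu[2])
    ll <- ll - log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(x) %*% Sinv %*% x)
    ll <- ll + log(2) + dnorm(item$a[j], log = TRUE)
    ll <- ll + log(2) + dnorm(1 / item$sigma[j], log = TRUE)
    if (model %in% c("sathm", "rmhm"))
      ll <- ll + log(2) + dnorm(item$alpha[j], log = TRUE)
  }
  if (model == "sathm") ll <- ll + dnorm(zeta, log = TRUE)
  ll <- ll + dnorm(r, log = TRUE) - log(pnorm(1) - pnorm(-1))
  ll <- ll + sum(dnorm(hyper$mu, 0, sqrt(1000), log = TRUE))
  # inverse-Wishart(I2, nu = 2) log density
  nu <- 2; p <- 2
  ll <- ll - 0.5 * nu * p * log(2) -
    (0.5 * log(pi) + lgamma(nu / 2) + lgamma((nu - 1) / 2)) -
    0.5 * (nu + p + 1) * log(det(S)) - 0.5 * sum(diag(solve(S)))
  ll
}

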