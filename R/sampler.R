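#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler. Defaults follow the
#' reference estimation protocol: 30000 iterations with a 10000-iteration
#' burn-in, 2 chains, thinning by 2.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded (also the adaptation window: proposal
#'   scales adapt in batches during burn-in and are frozen afterwards).
#' @param n_chains number of chains (>= 2 needed for the PSRF diagnostic).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer; chain c runs under `seed + c - 1`.
#' @param alpha_truncated logical; if TRUE (default) the residual-time slopes
#'   alpha_j get the left-truncated N(0,1)I(0,Inf) prior; if FALSE an
#'   untruncated N(0,1), which permits negative time effects.
#' @param adapt_batch adaptation batch length in iterations.
#' @param vague_var prior variance of the vague normal hyperpriors on
#'   (mu_b, mu_beta).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 30000, burn_in = 10000, n_chains = 2,
                        thin = 2, seed = 1L, alpha_truncated = TRUE,
                        adapt_batch = 50, vague_var = 1000) {
  stopifnot(n_iter > 0, burn_in >= 0, burn_in < n_iter, thin >= 1,
            n_chains >= 1, adapt_batch >= 1, vague_var > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed), alpha_truncated = alpha_truncated,
                 adapt_batch = as.integer(adapt_batch), vague_var = vague_var),
            class = "mcmc_config")
}

model_code <- function(model) {
  switch(model, m0 = 0L, rmhm = 1L, sathm = 2L, rtonly = 3L,
         stop("unknown model tag: ", model))
}

par_names <- function(N, J) {
  c(sprintf("theta[%d]", seq_len(N)), sprintf("tau[%d]", seq_len(N)),
    sprintf("a[%d]", seq_len(J)), sprintf("b[%d]", seq_len(J)),
    sprintf("beta[%d]", seq_len(J)), sprintf("sigma[%d]", seq_len(J)),
    sprintf("alpha[%d]", seq_len(J)),
    "zeta", "rho", "mu_b", "mu_beta", "sigma_b2", "sigma_bbeta", "sigma_beta2")
}

# Deterministic method-of-moments initialization from the data; per-chain
# dispersion is added by run_mcmc under the chain's seed.
init_state <- function(U, logT, obs) {
  Un <- U; Un[!obs] <- NA
  Tn <- logT; Tn[!obs] <- NA
  pc <- rowMeans(Un, na.rm = TRUE)
  pc <- pmin(pmax(pc, 0.02), 0.98)
  theta0 <- as.numeric(scale(stats::qlogis(pc)))
  theta0[!is.finite(theta0)] <- 0
  mt <- rowMeans(Tn, na.rm = TRUE)
  tau0 <- -(mt - mean(mt))
  sdt <- stats::sd(tau0)
  if (is.finite(sdt) && sdt > 1e-8) tau0 <- tau0 / sdt
  beta0 <- colMeans(Tn + tau0, na.rm = TRUE)
  res <- sweep(Tn + tau0, 2, beta0)
  sigma0 <- pmax(apply(res, 2, stats::sd, na.rm = TRUE), 0.2)
  pj <- pmin(pmax(colMeans(Un, na.rm = TRUE), 0.02), 0.98)
  b0 <- -stats::qlogis(pj)
  rho0 <- stats::cor(theta0, tau0)
  if (!is.finite(rho0)) rho0 <- 0
  Sg0 <- stats::cov(cbind(b0, beta0)) + diag(0.1, 2)
  list(theta = theta0, tau = tau0, a = rep(1, length(b0)), b = b0,
       beta = beta0, sigma = sigma0, alpha = rep(0.5, length(b0)),
       zeta = 1, rho = max(min(rho0, 0.9), -0.9),
       mu = c(mean(b0), mean(beta0)), Sigma_I = Sg0)
}

jitter_init <- function(init, model) {
  N <- length(init$theta); J <- length(init$a)
  init$theta <- init$theta + stats::rnorm(N, 0, 0.3)
  init$tau <- init$tau + stats::rnorm(N, 0, 0.3)
  init$a <- init$a * exp(stats::rnorm(J, 0, 0.2))
  init$b <- init$b + stats::rnorm(J, 0, 0.2)
  init$beta <- init$beta + stats::rnorm(J, 0, 0.1)
  init$sigma <- init$sigma * exp(stats::rnorm(J, 0, 0.1))
  init$alpha <- init$alpha * exp(stats::rnorm(J, 0, 0.2))
  init$zeta <- init$zeta + stats::rnorm(1, 0, 0.2)
  init$rho <- max(min(init$rho + stats::rnorm(1, 0, 0.05), 0.95), -0.95)
  if (model == "m0") { init$alpha <- rep(0, J); init$zeta <- 0 }
  if (model == "rmhm") init$zeta <- 0
  if (model == "rtonly") { init$alpha <- rep(0, J); init$zeta <- 0; init$a <- rep(1, J) }
  init
}

#' Fit a joint response/response-time hierarchical model by MCMC
#'
#' Runs independent Metropolis-within-Gibbs chains for the requested response
#' submodel — `"sathm"` (speed-accuracy tradeoff), `"rmhm"` (response
#' moderation), `"m0"` (independent 2PL), or `"rtonly"` (response-time
#' likelihood only, for validation) — sharing the lognormal response-time
#' submodel and the hierarchical person/item structure.
#'
#' Person parameters are identified by construction: their prior is bivariate
#' normal with means 0 and variances 1, so the covariance `rho` is the
#' ability-speed correlation. Items get the hierarchical bivariate normal
#' prior on (b, beta) with conjugate updates of its mean and inverse-Wishart
#' covariance; a_j, 1/sigma_j (and alpha_j by default) get left-truncated
#' standard normal priors, zeta a standard normal, rho a standard normal
#' doubly truncated to (-1, 1).
#'
#' @param dataset a `sathm_data` object ([generate_dataset()] or
#'   [read_dataset()]).
#' @param model response submodel tag.
#' @param config an [mcmc_config()].
#' @return An object of class `sathm_fit`: list with `summary` (data.frame of
#'   posterior mean/sd/95% credible interval per parameter), `draws` (list of
#'   per-chain matrices, post burn-in and thinned), `psrf` (multivariate PSRF
#'   over item-level and hyper parameters), `psrf_max_univariate`, `dic`
#'   (joint-deviance convention) and `dic_response` (response-only deviance),
#'   `accept`, `converged`, `model`, `config`.
#' @export
run_mcmc <- function(dataset, model = c("sathm", "rmhm", "m0", "rtonly"),
                     config = mcmc_config()) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "sathm_data"), inherits(config, "mcmc_config"))
  U <- dataset$responses
  obs <- dataset$mask
  if (sum(obs) == 0) stop("dataset has no observed cells")
  logT <- if (!is.null(dataset$log_times)) dataset$log_times else log(dataset$times)
  logT[!obs] <- 0
  U2 <- U; U2[!obs] <- 0L
  N <- nrow(U); J <- ncol(U)
  init0 <- init_state(U, logT, obs)
  ctrl <- list(n_iter = config$n_iter, burn_in = config$burn_in,
               thin = config$thin, alpha_truncated = config$alpha_truncated,
               adapt_batch = config$adapt_batch, vague_var = config$vague_var)
  pn <- par_names(N, J)
  draws <- vector("list", config$n_chains)
  devJ <- devR <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    ini <- jitter_init(init0, model)
    res <- sathm_chain_cpp(U2, logT, as_int_matrix(obs), model_code(model),
                           ini, ctrl)
    colnames(res$draws) <- pn
    draws[[ch]] <- res$draws
    devJ[[ch]] <- as.numeric(res$dev_joint)
    devR[[ch]] <- as.numeric(res$dev_resp)
    accept[[ch]] <- res$accept
  }
  pooled <- do.call(rbind, draws)
  est <- colMeans(pooled)
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  summ <- data.frame(parameter = pn, mean = est,
                     sd = apply(pooled, 2, stats::sd),
                     lower = qs[1, ], upper = qs[2, ], row.names = NULL)

  # convergence: multivariate PSRF over the test-level and hyper parameters
  # (zeta, rho, item means and covariance). The largest-eigenvalue statistic
  # is upward-biased when the dimension is comparable to the effective sample
  # size, so the high-dimensional person/item blocks are monitored through
  # the maximum univariate R-hat instead.
  psrf_mv <- NA_real_
  psrf_max <- NA_real_
  if (config$n_chains >= 2) {
    keep_cols <- (2 * N + 5 * J + 1):length(pn)
    vr <- apply(pooled[, keep_cols, drop = FALSE], 2, stats::var)
    sub <- keep_cols[vr > 1e-12]
    if (length(sub) >= 1 && nrow(draws[[1]]) >= 10)
      psrf_mv <- tryCatch(psrf(lapply(draws, function(d) d[, sub, drop = FALSE])),
                          error = function(e) NA_real_)
    vall <- apply(pooled, 2, stats::var)
    nz <- which(vall > 1e-12)
    if (length(nz) && nrow(draws[[1]]) >= 10)
      psrf_max <- max(psrf_univariate(draws, nz))
  }

  pm <- posterior_mean_state(summ, N, J)
  ll <- loglik_sums_cpp(U2, logT, as_int_matrix(obs), model_code(model),
                        pm$theta, pm$tau, pm$a, pm$b, pm$beta, pm$sigma,
                        pm$alpha, pm$zeta)
  dev_at_mean_joint <- -2 * (ll$resp + ll$rt)
  dev_at_mean_resp <- -2 * ll$resp
  dic_joint <- dic(unlist(devJ), dev_at_mean_joint)
  dic_resp <- dic(unlist(devR), dev_at_mean_resp)

  out <- list(model = model, config = config, summary = summ, draws = draws,
              deviance_joint = unlist(devJ), deviance_response = unlist(devR),
              dic = dic_joint, dic_response = dic_resp,
              psrf = psrf_mv, psrf_max_univariate = psrf_max,
              converged = is.finite(psrf_mv) && psrf_mv < 1.1,
              accept = accept[[1]], n_persons = N, n_items = J,
              deviance_convention = "joint (responses and response times)")
  class(out) <- "sathm_fit"
  out
}

as_int_matrix <- function(m) { storage.mode(m) <- "integer"; m }

posterior_mean_state <- function(summ, N, J) {
  g <- function(nm, k) summ$mean[match(sprintf("%s[%d]", nm, seq_len(k)), summ$parameter)]
  s1 <- function(nm) summ$mean[match(nm, summ$parameter)]
  list(theta = g("theta", N), tau = g("tau", N), a = g("a", J), b = g("b", J),
       beta = g("beta", J), sigma = g("sigma", J), alpha = g("alpha", J),
       zeta = s1("zeta"), rho = s1("rho"),
       mu = c(s1("mu_b"), s1("mu_beta")),
       Sigma_I = matrix(c(s1("sigma_b2"), s1("sigma_bbeta"),
                          s1("sigma_bbeta"), s1("sigma_beta2")), 2, 2))
}

#' Extract posterior means of a parameter family from a fit
#'
#' @param fit a `sathm_fit`.
#' @param family one of "theta", "tau", "a", "b", "beta", "sigma", "alpha",
#'   "zeta", "rho", "mu_b", "mu_beta", "sigma_b2", "sigma_bbeta",
#'   "sigma_beta2".
#' @return Numeric vector of posterior means.
#' @export
posterior_means <- function(fit, family) {
  stopifnot(inherits(fit, "sathm_fit"))
  if (family %in% c("zeta", "rho", "mu_b", "mu_beta",
                    "sigma_b2", "sigma_bbeta", "sigma_beta2"))
    return(fit$summary$mean[match(family, fit$summary$parameter)])
  idx <- grep(paste0("^", family, "\\["), fit$summary$parameter)
  if (!length(idx)) stop("unknown parameter family: ", family)
  fit$summary$mean[idx]
}

#' @export
print.sathm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical response/response-time model fit: %s\n", toupper(x$model)))
  cat(sprintf("  %d persons x %d items; %d chains x %d kept draws\n",
              x$n_persons, x$n_items, length(x$draws), nrow(x$draws[[1]])))
  cat(sprintf("  DIC (joint deviance) = %.2f  (D_bar = %.2f, p_D = %.2f)\n",
              x$dic$DIC, x$dic$D_bar, x$dic$p_D))
  cat(sprintf("  multivariate PSRF = %.4f (%s)\n", x$psrf,
              if (isTRUE(x$converged)) "converged" else "NOT converged at 1.1"))
  hp <- c("rho", "zeta", "mu_b", "mu_beta", "sigma_b2", "sigma_bbeta", "sigma_beta2")
  print(x$summary[x$summary$parameter %in% hp, ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multivariate potential scale reduction factor
#'
#' Brooks-Gelman multivariate PSRF across chains:
#' `(n-1)/n + ((m+1)/m) * lambda_1`, where `lambda_1` is the largest
#' eigenvalue of `W^{-1} B / n`, with `W` the mean within-chain covariance
#' and `B/n` the between-chain covariance of the chain means. Values near 1
#' indicate the chains mix over a common distribution; above about 1.1 the
#' chains have not converged.
#'
#' @param chains list of at least two chains; each a numeric matrix
#'   (iterations x parameters) or vector.
#' @return Scalar PSRF (>= about 1 up to sampling noise).
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need at least 2 chains")
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1) else as.matrix(ch)
  })
  n <- nrow(chains[[1]]); p <- ncol(chains[[1]])
  if (any(vapply(chains, nrow, 1L) != n)) stop("chains must have equal length")
  if (n < 10) stop("need at least 10 draws per chain")
  m <- length(chains)
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  mus <- do.call(rbind, lapply(chains, colMeans))
  Bn <- stats::cov(mus)                      # B/n
  if (p == 1) {
    lam <- as.numeric(Bn) / as.numeric(W)
  } else {
    M <- solve(W, Bn)
    lam <- max(Re(eigen(M, only.values = TRUE)$values))
  }
  (n - 1) / n + (m + 1) / m * lam
}

# univariate split-free Gelman-Rubin R-hat for a set of columns
psrf_univariate <- function(draws, cols) {
  n <- nrow(draws[[1]]); m <- length(draws)
  W <- Reduce(`+`, lapply(draws, function(d) apply(d[, cols, drop = FALSE], 2, stats::var))) / m
  mus <- do.call(rbind, lapply(draws, function(d) colMeans(d[, cols, drop = FALSE])))
  Bn <- apply(mus, 2, stats::var)
  sqrt(((n - 1) / n * W + (1 + 1 / m) * Bn) / W)
}

#' Deviance information criterion from MCMC deviance draws
#'
#' `D_bar` is the posterior mean of the deviance (-2 log-likelihood) over
#' retained draws, `p_D = D_bar - D(posterior means)` the effective number of
#' parameters, and `DIC = D_bar + p_D`. Smaller is better.
#'
#' @param deviance_draws numeric vector of per-draw deviances.
#' @param deviance_at_mean deviance evaluated at the posterior means.
#' @return List with `D_bar`, `p_D`, `DIC`.
#' @export
dic <- function(deviance_draws, deviance_at_mean) {
  if (!length(deviance_draws)) stop("empty deviance draws")
  if (anyNA(deviance_draws) || any(!is.finite(deviance_draws)) ||
      !is.finite(deviance_at_mean))
    stop("non-finite deviance")
  D_bar <- mean(deviance_draws)
  p_D <- D_bar - deviance_at_mean
  list(D_bar = D_bar, p_D = p_D, DIC = D_bar + p_D)
}

#' Unnormalized log posterior density (pure-R reference)
#'
#' Term-by-term sum of the response likelihood (per model tag), the lognormal
#' response-time likelihood, the bivariate normal person prior, the
#' hierarchical bivariate normal item prior for (b, beta), the truncated /
#' untruncated scalar priors, and the hyperpriors (vague normal means,
#' inverse-Wishart item covariance). The residual SD enters through the
#' sampled coordinate 1/sigma (left-truncated standard normal prior on
#' 1/sigma, no Jacobian), matching the sampler's parameterization.
#'
#' This function is a readable reference implementation used to validate the
#' compiled sampler; it is not called in the sampling loop.
#'
#' @param dataset a `sathm_data`.
#' @param item data.frame with columns a, b, beta, sigma, alpha.
#' @param zeta scalar intercept of the residual-time effect.
#' @param person data.frame with columns theta, tau.
#' @param hyper list with `sigma_theta_tau`, `mu` (length 2), `Sigma_I` (2x2).
#' @param model response submodel tag.
#' @param alpha_truncated logical, as in [mcmc_config()].
#' @return Scalar log density; `-Inf` for out-of-support parameters.
#' @export
log_joint <- function(dataset, item, zeta, person, hyper,
                      model = c("sathm", "rmhm", "m0", "rtonly"),
                      alpha_truncated = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "sathm_data"))
  if (any(item$a <= 0) || any(item$sigma <= 0) ||
      abs(hyper$sigma_theta_tau) >= 1 ||
      (alpha_truncated && model %in% c("sathm", "rmhm") && any(item$alpha <= 0)))
    return(-Inf)
  S <- hyper$Sigma_I
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(-Inf)

  obs <- dataset$mask
  U <- dataset$responses
  logT <- if (!is.null(dataset$log_times)) dataset$log_times else log(dataset$times)
  N <- nrow(U); J <- ncol(U)
  TH <- matrix(person$theta, N, J)
  TA <- matrix(person$tau, N, J)
  A <- rep_row(item$a, N); B <- rep_row(item$b, N)
  BE <- rep_row(item$beta, N); SG <- rep_row(item$sigma, N)
  AL <- rep_row(item$alpha, N)
  Z <- (logT - (BE - TA)) / SG

  ll_rt <- sum(stats::dnorm(logT[obs], mean = (BE - TA)[obs], sd = SG[obs],
                            log = TRUE) - logT[obs])
  ll_resp <- if (model == "rtonly") 0 else {
    p <- switch(model,
      sathm = satm_prob(TH[obs], A[obs], B[obs], AL[obs], Z[obs], zeta),
      rmhm = rmm_prob(TH[obs], A[obs], B[obs], AL[obs], Z[obs]),
      m0 = two_pl(TH[obs], A[obs], B[obs]))
    sum(ifelse(U[obs] == 1, log(p), log1p(-p)))
  }

  r <- hyper$sigma_theta_tau
  lp_person <- sum(dbvnorm(person$theta, person$tau, 0, 0, 1, 1, r))
  lp_item_bb <- sum(dbvnorm(item$b, item$beta, hyper$mu[1], hyper$mu[2],
                            S[1, 1], S[2, 2], S[1, 2] / sqrt(S[1, 1] * S[2, 2])))
  lp_trunc <- sum(stats::dnorm(item$a, log = TRUE) + log(2)) +
    sum(stats::dnorm(1 / item$sigma, log = TRUE) + log(2))
  lp_alpha <- if (model %in% c("sathm", "rmhm")) {
    if (alpha_truncated) sum(stats::dnorm(item$alpha, log = TRUE) + log(2))
    else sum(stats::dnorm(item$alpha, log = TRUE))
  } else 0
  lp_zeta <- if (model == "sathm") stats::dnorm(zeta, log = TRUE) else 0
  lp_rho <- stats::dnorm(r, log = TRUE) -
    log(stats::pnorm(1) - stats::pnorm(-1))
  lp_mu <- sum(stats::dnorm(hyper$mu, 0, sqrt(1000), log = TRUE))
  lp_Sig <- dinvwishart2(S, nu = 2, Psi = diag(2))

  ll_resp + ll_rt + lp_person + lp_item_bb + lp_trunc + lp_alpha +
    lp_zeta + lp_rho + lp_mu + lp_Sig
}

# bivariate normal log density (vectorized over x, y)
dbvnorm <- function(x, y, mx, my, vx, vy, r) {
  sx <- sqrt(vx); sy <- sqrt(vy)
  zx <- (x - mx) / sx; zy <- (y - my) / sy
  q <- (zx^2 - 2 * r * zx * zy + zy^2) / (1 - r^2)
  -log(2 * pi) - log(sx * sy) - 0.5 * log(1 - r^2) - q / 2
}

# inverse-Wishart log density, p = 2
dinvwishart2 <- function(S, nu, Psi) {
  p <- 2
  lgamma2 <- 0.5 * log(pi) + lgamma(nu / 2) + lgamma((nu - 1) / 2)
  0.5 * nu * as.numeric(determinant(Psi)$modulus) - 0.5 * nu * p * log(2) -
    lgamma2 -
    0.5 * (nu + p + 1) * as.numeric(determinant(S)$modulus) -
    0.5 * sum(diag(Psi %*% solve(S)))
}
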