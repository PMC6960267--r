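# Small hand-built fixtures used across test files.

# A well-behaved truth object (residual SDs O(1)) for sampler-level tests,
# bypassing the heavy-tailed reciprocal-truncated-normal sigma draws.
make_truth <- function(N, J, seed = 1, alpha = NULL, zeta = 0.5,
                       model = "sathm", rho = 0.5) {
  set.seed(seed)
  design <- sim_design(n_persons = N, n_items = J, generating_model = model,
                       sigma_theta_tau = rho, seed = seed)
  person <- draw_persons(design)
  item <- data.frame(
    a = runif(J, 0.6, 1.6),
    b = rnorm(J, 0, 1),
    beta = rnorm(J, 3, 0.5),
    sigma = runif(J, 0.5, 1.5),
    alpha = if (is.null(alpha)) runif(J, 0.3, 1.2) else rep(alpha, J))
  structure(list(item = item, zeta = zeta, person = person,
                 sigma_theta_tau = rho, design = design),
            class = "sim_truth")
}

short_config <- function(n_iter = 600, burn_in = 200, seed = 1, ...) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, seed = seed, ...)
}

# toy dataset for I/O and log-joint tests
toy_dataset <- function(seed = 42, N = 3, J = 2) {
  tr <- make_truth(N, J, seed = seed)
  generate_dataset(tr, seed = seed + 1)
}
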