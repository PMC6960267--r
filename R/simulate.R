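#' Simulation design for the joint response/response-time model
#'
#' Bundles the generating conditions of the parameter-recovery simulation:
#' sample size, test length, the person-level ability-speed correlation, the
#' item-level mean vector and covariance of (difficulty, time intensity),
#' the generating model, and a seed.
#'
#' Defaults follow the recovery-study conditions: items drawn with
#' discrimination, reciprocal residual SD and residual-time slope from a
#' standard normal truncated to (0, Inf), test intercept standard normal,
#' (b, beta) bivariate normal with mean (0, 3) and covariance
#' matrix(c(1, .25, .25, .25), 2); persons bivariate standard normal with
#' correlation 0.5.
#'
#' @param n_persons number of examinees N.
#' @param n_items test length m.
#' @param sigma_theta_tau generating ability-speed correlation, in (-1, 1).
#' @param item_mean length-2 mean of (difficulty b, time intensity beta).
#' @param item_cov 2x2 positive-definite covariance of (b, beta).
#' @param generating_model one of "sathm", "rmhm", "m0".
#' @param seed integer seed used by the draw functions.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_persons = 500, n_items = 30,
                       sigma_theta_tau = 0.5,
                       item_mean = c(0, 3),
                       item_cov = matrix(c(1, 0.25, 0.25, 0.25), 2, 2),
                       generating_model = c("sathm", "rmhm", "m0"),
                       seed = 1L) {
  generating_model <- match.arg(generating_model)
  stopifnot(n_persons >= 2, n_items >= 2,
            is.numeric(sigma_theta_tau), length(sigma_theta_tau) == 1,
            abs(sigma_theta_tau) < 1,
            length(item_mean) == 2, all(dim(item_cov) == c(2, 2)))
  if (abs(item_cov[1, 2] - item_cov[2, 1]) > 1e-12 ||
      any(eigen(item_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("'item_cov' must be symmetric positive definite")
  structure(list(n_persons = as.integer(n_persons),
                 n_items = as.integer(n_items),
                 sigma_theta_tau = sigma_theta_tau,
                 item_mean = as.numeric(item_mean),
                 item_cov = item_cov,
                 generating_model = generating_model,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# Inverse-CDF draw from N(0,1) truncated to (0, Inf); platform-stable given
# the RNG stream.
rtnorm_pos <- function(n) {
  stats::qnorm(0.5 + 0.5 * stats::runif(n))
}

#' Draw item and test parameters from the generating distributions
#'
#' Discrimination a, reciprocal residual SD 1/sigma and residual-time slope
#' alpha are standard normal truncated to (0, Inf) (inverse-CDF sampling);
#' the test intercept zeta is standard normal; (b, beta) are bivariate
#' normal with the design's mean and covariance. sigma is stored as the
#' reciprocal of the truncated-normal draw.
#'
#' @param design a [sim_design()].
#' @return List with `item` (data.frame: a, b, beta, sigma, alpha) and
#'   `zeta` (scalar).
#' @export
draw_items <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  m <- design$n_items
  a <- rtnorm_pos(m)
  inv_sigma <- rtnorm_pos(m)
  alpha <- rtnorm_pos(m)
  zeta <- stats::rnorm(1)
  bb <- mvn_draw(m, design$item_mean, design$item_cov)
  list(item = data.frame(a = a, b = bb[, 1], beta = bb[, 2],
                         sigma = 1 / inv_sigma, alpha = alpha),
       zeta = zeta)
}

#' Draw person parameters from the generating distribution
#'
#' (theta, tau) are bivariate normal with means 0, variances 1 and
#' correlation `design$sigma_theta_tau` — the identification restrictions of
#' the hierarchical model, under which the covariance equals the
#' correlation.
#'
#' @param design a [sim_design()].
#' @return data.frame with columns `theta`, `tau`.
#' @export
draw_persons <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  r <- design$sigma_theta_tau
  S <- matrix(c(1, r, r, 1), 2, 2)
  p <- mvn_draw(design$n_persons, c(0, 0), S)
  data.frame(theta = p[, 1], tau = p[, 2])
}

mvn_draw <- function(n, mean, cov) {
  L <- chol(cov)
  z <- matrix(stats::rnorm(n * 2), n, 2)
  sweep(z %*% L, 2, mean, `+`)
}

#' Draw a full set of generating values ("truth") for one replication
#'
#' @param design a [sim_design()]. The design's seed initializes the RNG;
#'   pass `seed` to override (e.g. per replication).
#' @param seed optional integer overriding `design$seed`.
#' @return An object of class `sim_truth`: list with `item`, `zeta`,
#'   `person`, `sigma_theta_tau`, `design`.
#' @export
draw_truth <- function(design, seed = design$seed) {
  set.seed(seed)
  it <- draw_items(design)
  pe <- draw_persons(design)
  structure(list(item = it$item, zeta = it$zeta, person = pe,
                 sigma_theta_tau = design$sigma_theta_tau, design = design),
            class = "sim_truth")
}

#' Generate a response/response-time dataset from generating values
#'
#' For each person-item cell, draws a log response time from the lognormal
#' response-time model, computes the standardized residual Z from the *true*
#' parameters, and draws the binary response from the generating model's
#' response probability (speed-accuracy tradeoff, response moderation, or
#' plain 2PL). All cells are observed (the mask exists to support empirical
#' data with missingness, which is not simulated).
#'
#' @param truth a [draw_truth()] result.
#' @param seed integer seed for the data draw.
#' @return An object of class `sathm_data`: list with `responses` (N x m
#'   0/1 matrix), `times` (N x m seconds), `mask` (N x m logical),
#'   `person_ids`, `item_ids`.
#' @export
generate_dataset <- function(truth, seed = truth$design$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  it <- truth$item; pe <- truth$person
  N <- nrow(pe); m <- nrow(it)
  eps <- matrix(stats::rnorm(N * m), N, m)
  mu <- outer(-pe$tau, it$beta, `+`)            # beta_j - tau_i
  logT <- mu + sweep(eps, 2, it$sigma, `*`)
  z <- eps                                       # (logT - mu)/sigma by construction
  theta <- pe$theta
  p <- switch(truth$design$generating_model,
    sathm = satm_prob(theta, rep_row(it$a, N), rep_row(it$b, N),
                      rep_row(it$alpha, N), z, truth$zeta),
    rmhm  = rmm_prob(theta, rep_row(it$a, N), rep_row(it$b, N),
                     rep_row(it$alpha, N), z),
    m0    = matrix(two_pl(rep(theta, m), rep_row(it$a, N), rep_row(it$b, N)), N, m))
  p <- matrix(p, N, m)
  U <- matrix(as.integer(stats::runif(N * m) < p), N, m)
  new_sathm_data(U, exp(logT), matrix(TRUE, N, m),
                 person_ids = sprintf("p%04d", seq_len(N)),
                 item_ids = sprintf("i%03d", seq_len(m)),
                 log_times = logT)
}

# recycle an item-length vector across N rows of an N x m matrix
rep_row <- function(v, N) matrix(v, N, length(v), byrow = TRUE)

# log_times is the canonical compute-scale copy of times: with the
# reciprocal-truncated-normal residual SDs of the generating design, sigma can
# be large enough that exp(logT) overflows double for a rare cell.
new_sathm_data <- function(responses, times, mask, person_ids, item_ids,
                           log_times = log(times)) {
  storage.mode(responses) <- "integer"
  stopifnot(all(dim(responses) == dim(times)), all(dim(times) == dim(mask)))
  if (any(!is.finite(log_times[mask]))) stop("observed times must be > 0")
  if (any(!responses[mask] %in% c(0L, 1L))) stop("observed responses must be 0/1")
  structure(list(responses = responses, times = times, mask = mask,
                 person_ids = person_ids, item_ids = item_ids,
                 log_times = log_times),
            class = "sathm_data")
}

#' @export
print.sathm_data <- function(x, ...) {
  cat(sprintf("Joint response/response-time dataset: %d persons x %d items (%d observed cells)\n",
              nrow(x$responses), ncol(x$responses), sum(x$mask)))
  cat(sprintf("  proportion correct %.3f, median time %.2f s\n",
              mean(x$responses[x$mask]),
              exp(stats::median(x$log_times[x$mask]))))
  invisible(x)
}
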