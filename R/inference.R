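#' Doubly Bayesian inference of internal models
#'
#' The experimenter performs Bayesian inference over the parameters of a
#' participant who is herself modelled as a Bayesian filter: the joint
#' posterior over the internal-model parameters (`pi`, `phi`) and the LATER
#' response-time parameters (`theta0`, `mu`, `sigma`) is sampled given the
#' stimulus sequence and the valid response times. The nonparametric prior
#' over the transition structure is implemented as a finite truncation at
#' `k_max` states with a remainder component whose prior weight is scaled by
#' a slicing variable `eps ~ Uniform(0.02, 0.2)`, resampled every outer step
#' of the chain; in between, gradient-based No-U-Turn updates move the
#' continuous parameters. During filtering only the states covering the
#' belief's `1 - eps` support are retained.
#'
#' @name inference
NULL

#' Hyperparameters of the truncated hierarchical Dirichlet process prior
#'
#' @param alpha concentration of the per-row Dirichlet process (1.3).
#' @param gamma top-level concentration (3.8); carried as metadata for the
#'   full stick-breaking construction, which the truncated prior summarizes.
#' @param emission_base Dirichlet pseudo-counts for emission rows.
#' @param k_max truncation level of the state space (default 12, comfortably
#'   above the 8-state ideal observer).
#' @param alpha0 row concentration of the truncated transition prior
#'   `Dirichlet(alpha0/K, ..., alpha0/K, alpha0/K * eps)`; defaults to
#'   `alpha`.
#' @param rt_priors list of `c(shape, rate)` pairs for `theta0`, `mu`,
#'   `sigma`, interpreted with time in seconds (so `Gamma(1, 10)` puts the
#'   offset's prior mean at 0.1 s and `Gamma(1, 0.1)` the rate mean at
#'   10 1/s, the human response-time scale).
#' @return Object of class `hdp_hyper`.
#' @export
hdp_hyper <- function(alpha = 1.3, gamma = 3.8,
                      emission_base = rep(0.8, 4), k_max = 12L,
                      alpha0 = alpha,
                      rt_priors = list(theta0 = c(1, 10), mu = c(1, 0.1),
                                       sigma = c(1, 0.01))) {
  stopifnot(alpha > 0, gamma > 0, all(emission_base > 0), k_max >= 2,
            alpha0 > 0)
  structure(list(alpha = alpha, gamma = gamma,
                 emission_base = emission_base, k_max = as.integer(k_max),
                 alpha0 = alpha0, rt_priors = rt_priors),
            class = "hdp_hyper")
}

#' Fit configuration
#'
#' The `full` preset reproduces the reference sampling schedule (4 chains,
#' 1600 outer slice steps, 30 inner NUTS steps); the `desk` preset is a
#' reduced schedule for interactive use and testing (2 chains, 200 outer,
#' 5 inner).
#'
#' @param preset `"full"` or `"desk"`; sets the chain counts below unless
#'   overridden.
#' @param n_chains,n_outer_steps,n_inner_steps sampling schedule.
#' @param n_prediction_samples_per_chain retained unique samples per chain
#'   used for prediction (performance saturates around 60).
#' @param train_blocks,test_blocks block sets used for fitting and held-out
#'   evaluation; must be disjoint.
#' @param rt_floor_ms fast-response cutoff: response times below this are
#'   excluded from the likelihood (express responses come from a different
#'   process and are cut rather than modelled).
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param max_tree_depth NUTS doubling cap.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(preset = c("desk", "full"),
                       n_chains = NULL, n_outer_steps = NULL,
                       n_inner_steps = NULL,
                       n_prediction_samples_per_chain = 60L,
                       train_blocks = 11:20, test_blocks = 1:10,
                       rt_floor_ms = 180, seed = 1L,
                       max_tree_depth = NULL) {
  preset <- match.arg(preset)
  defaults <- if (preset == "full") c(4L, 1600L, 30L) else c(2L, 200L, 5L)
  # the desk preset caps the NUTS doubling earlier; see the methods vignette
  if (is.null(max_tree_depth)) max_tree_depth <- if (preset == "full") 8L else 5L
  n_chains <- as.integer(if (is.null(n_chains)) defaults[1] else n_chains)
  n_outer_steps <- as.integer(if (is.null(n_outer_steps)) defaults[2] else n_outer_steps)
  n_inner_steps <- as.integer(if (is.null(n_inner_steps)) defaults[3] else n_inner_steps)
  if (length(intersect(train_blocks, test_blocks)) > 0) {
    stop("train and test blocks must be disjoint", call. = FALSE)
  }
  stopifnot(n_chains >= 1, n_outer_steps >= 1, n_inner_steps >= 1,
            n_prediction_samples_per_chain >= 1, rt_floor_ms >= 0)
  structure(list(preset = preset, n_chains = n_chains,
                 n_outer_steps = n_outer_steps,
                 n_inner_steps = n_inner_steps,
                 n_prediction_samples_per_chain =
                   as.integer(n_prediction_samples_per_chain),
                 train_blocks = train_blocks, test_blocks = test_blocks,
                 rt_floor_ms = rt_floor_ms, seed = as.integer(seed),
                 max_tree_depth = as.integer(max_tree_depth)),
            class = "fit_config")
}

#' Valid-trial mask for the response-time likelihood
#'
#' A trial's response time enters the likelihood only if the trial is not a
#' warm-up trial, the response was correct, and the response time is at or
#' above the fast cutoff. Stimuli of masked trials still drive the belief
#' filter.
#'
#' @param trials trial table with columns `trial_type`, `correct`, `rt_ms`.
#' @param config a [fit_config()].
#' @return Logical vector, `TRUE` where the response time is usable.
#' @export
valid_trial_mask <- function(trials, config = fit_config()) {
  need <- c("trial_type", "correct", "rt_ms")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mask <- trials$trial_type != "warmup" &
    !is.na(trials$correct) & trials$correct == 1 &
    !is.na(trials$rt_ms) & trials$rt_ms >= config$rt_floor_ms
  if (!any(mask)) {
    warning("no valid trials: every response time is excluded", call. = FALSE)
  }
  mask
}

#' A single posterior sample
#'
#' @param hmm an [hmm_params()].
#' @param later a [later_params()].
#' @param slice_eps the slicing variable in force when the sample was drawn
#'   (`NA` for models sampled without slice truncation).
#' @param chain,step chain id and outer-step index.
#' @param lp unnormalized log joint at the sample (optional).
#' @param occupied number of latent states carrying appreciable belief mass
#'   (optional diagnostic).
#' @return Object of class `posterior_sample`.
#' @export
posterior_sample <- function(hmm, later, slice_eps = NA_real_, chain = 1L,
                             step = 1L, lp = NA_real_, occupied = NA_integer_) {
  stopifnot(inherits(hmm, "hmm_params"), inherits(later, "later_params"))
  if (!is.na(slice_eps) && (slice_eps < 0.02 || slice_eps > 0.2)) {
    stop("slice_eps must lie in [0.02, 0.2]", call. = FALSE)
  }
  structure(list(hmm = hmm, later = later, slice_eps = slice_eps,
                 chain = as.integer(chain), step = as.integer(step),
                 lp = lp, occupied = occupied),
            class = "posterior_sample")
}

# ---- transforms -----------------------------------------------------------

# anchored softmax: u in R^{K-1} -> simplex in R^K (last component anchored)
softmax_row <- function(u) {
  e <- exp(c(u, 0) - max(c(u, 0)))
  e / sum(e)
}

row_to_u <- function(x) {
  x <- pmax(x, 1e-12)
  log(x[-length(x)]) - log(x[length(x)])
}

# log Dirichlet(a) density of softmax(u) plus the log Jacobian of the
# transform; gradient in u is a - sum(a) * x (anchored components only)
dirichlet_softmax_lp <- function(x, a) {
  sum(a * log(pmax(x, 1e-300))) + lgamma(sum(a)) - sum(lgamma(a))
}

# chain rule through the anchored softmax for a likelihood gradient g = dL/dx
softmax_chain <- function(g, x) {
  (x * (g - sum(g * x)))[-length(x)]
}

gamma_exp_lp <- function(v, shape, rate) {
  shape * log(rate) - lgamma(shape) + shape * v - rate * exp(v)
}

gamma_exp_grad <- function(v, shape, rate) shape - rate * exp(v)

# ---- parameter packing ----------------------------------------------------

pack_ct <- function(u_pi, u_phi, u_later) c(as.numeric(u_pi), as.numeric(u_phi), u_later)

unpack_ct <- function(theta, K) {
  n_pi <- K * (K - 1L)
  n_phi <- K * 3L
  list(u_pi = matrix(theta[seq_len(n_pi)], K, K - 1L),
       u_phi = matrix(theta[n_pi + seq_len(n_phi)], K, 3L),
       u_later = theta[n_pi + n_phi + 1:3])
}

theta_to_params <- function(theta, K, emission = NULL) {
  if (is.null(emission)) {
    up <- unpack_ct(theta, K)
    pi_m <- t(apply(up$u_pi, 1, softmax_row))
    phi_m <- t(apply(up$u_phi, 1, softmax_row))
    lat <- exp(up$u_later)
  } else {
    n_pi <- K * (K - 1L)
    u_pi <- matrix(theta[seq_len(n_pi)], K, K - 1L)
    pi_m <- t(apply(u_pi, 1, softmax_row))
    phi_m <- emission
    lat <- exp(theta[n_pi + 1:3])
  }
  list(transition = pi_m, emission = phi_m,
       later = later_params(lat[1], lat[2], lat[3]))
}

# ---- log joint ------------------------------------------------------------

pi_row_concentration <- function(hyper, K, eps) {
  a <- rep(hyper$alpha0 / K, K)
  if (!is.na(eps)) a[K] <- a[K] * eps
  a
}

dirichlet_lpdf <- function(x, a) {
  sum((a - 1) * log(pmax(x, 1e-300))) + lgamma(sum(a)) - sum(lgamma(a))
}

#' Log joint density of a posterior sample
#'
#' Sum of the transition-row prior (truncated Dirichlet with the remainder
#' component scaled by the sample's slicing variable), the emission-row
#' prior, the Gamma priors of the LATER parameters, and the response-time
#' likelihood of the valid trials evaluated at the filtered per-trial
#' predictive probabilities.
#'
#' @param sample a [posterior_sample()].
#' @param seq an `asrt_sequence` (or stimulus vector) covering the trials.
#' @param trials trial table aligned with `seq`, with `trial_type`,
#'   `correct`, `rt_ms`.
#' @param hyper an [hdp_hyper()].
#' @param config a [fit_config()].
#' @return Scalar log probability (finite for valid samples; an error names
#'   the offending term otherwise).
#' @export
log_joint <- function(sample, seq, trials, hyper = hdp_hyper(),
                      config = fit_config()) {
  hmm <- sample$hmm
  K <- hmm$n_states
  a_pi <- pi_row_concentration(hyper, K, sample$slice_eps)
  lp_pi <- sum(apply(hmm$transition, 1, dirichlet_lpdf, a = a_pi))
  identity_em <- isTRUE(all.equal(hmm$emission, diag(4), tolerance = 1e-12)) &&
    K == 4L
  lp_phi <- if (identity_em) 0 else
    sum(apply(hmm$emission, 1, dirichlet_lpdf, a = hyper$emission_base))
  rp <- hyper$rt_priors
  lat <- sample$later
  lp_rt_prior <- stats::dgamma(lat$theta0, rp$theta0[1], rp$theta0[2], log = TRUE) +
    stats::dgamma(lat$mu, rp$mu[1], rp$mu[2], log = TRUE) +
    stats::dgamma(lat$sigma, rp$sigma[1], rp$sigma[2], log = TRUE)
  lik <- rt_loglik(sample, seq, trials, config)
  terms <- c(transition_prior = lp_pi, emission_prior = lp_phi,
             rt_parameter_prior = lp_rt_prior, rt_likelihood = lik)
  if (any(!is.finite(terms))) {
    stop("non-finite log joint; offending term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "),
         call. = FALSE)
  }
  sum(terms)
}

# response-time log likelihood of the valid trials under one sample
rt_loglik <- function(sample, seq, trials, config) {
  y <- stimuli_of(seq)
  mask <- valid_trial_mask(trials, config)
  eps <- if (is.na(sample$slice_eps)) 0 else sample$slice_eps
  init <- as.numeric(stationary_belief(sample$hmm$transition))
  res <- ct_loglik_cpp(sample$hmm$transition, sample$hmm$emission,
                       as.integer(y), init, eps, as.integer(mask),
                       ifelse(is.na(trials$rt_ms), 0, trials$rt_ms) / 1000,
                       sample$later$theta0, sample$later$mu,
                       sample$later$sigma, P_FLOOR, 0L, FALSE)
  res$loglik
}

# ---- unconstrained log posterior + gradient -------------------------------

rt_prior_matrices <- function(hyper) {
  rp <- hyper$rt_priors
  list(shapes = c(rp$theta0[1], rp$mu[1], rp$sigma[1]),
       rates = c(rp$theta0[2], rp$mu[2], rp$sigma[2]))
}

# model = "ct": theta = (u_pi, u_phi, u_later); model = "markov": identity
# emissions, theta = (u_pi over 4 states, u_later); model = "stimulus":
# (u_pi, u_phi), stimulus predictive likelihood, no response-time block.
# All heavy lifting (transforms, priors, filtering, reverse-mode gradient)
# happens in the C++ kernel.
lp_grad_filtered <- function(theta, y, rt_s, mask, hyper, eps_slice, model) {
  K <- if (model == "markov") 4L else hyper$k_max
  model_code <- switch(model, ct = 0L, markov = 1L, stimulus = 2L)
  a_pi <- if (model == "markov") rep(hyper$alpha0 / 4, 4)
          else pi_row_concentration(hyper, K, eps_slice)
  pri <- rt_prior_matrices(hyper)
  lp_grad_cpp(theta, model_code, K, y, rt_s, as.integer(mask),
              if (is.na(eps_slice)) 0 else eps_slice, a_pi,
              hyper$emission_base, pri$shapes, pri$rates, P_FLOOR)
}

# ---- prior draws ----------------------------------------------------------

rdirichlet1 <- function(a) {
  x <- stats::rgamma(length(a), shape = a, rate = 1)
  if (sum(x) <= 0) x <- rep(1, length(a))
  x <- x / sum(x)
  # keep the unconstrained coordinates finite at initialization
  x <- pmax(x, 1e-4)
  x / sum(x)
}

draw_initial_theta <- function(hyper, model, eps_slice) {
  K <- if (model == "markov") 4L else hyper$k_max
  a_pi <- if (model == "markov") rep(hyper$alpha0 / 4, 4)
          else pi_row_concentration(hyper, K, eps_slice)
  u_pi <- t(vapply(seq_len(K), function(i) row_to_u(rdirichlet1(a_pi)),
                   numeric(K - 1L)))
  u_phi <- if (model == "markov") NULL else
    t(vapply(seq_len(K), function(i)
      row_to_u(rdirichlet1(hyper$emission_base)), numeric(3L)))
  if (model == "stimulus") return(c(as.numeric(u_pi), as.numeric(u_phi)))
  rp <- hyper$rt_priors
  lat <- c(stats::rgamma(1, rp$theta0[1], rp$theta0[2]),
           stats::rgamma(1, rp$mu[1], rp$mu[2]),
           stats::rgamma(1, rp$sigma[1], rp$sigma[2]))
  # keep initial draws on the physiological response-time scale so chains
  # start in a region of non-vanishing likelihood
  lat <- pmin(pmax(lat, c(0.01, 1, 0.2)), c(0.5, 40, 20))
  c(as.numeric(u_pi), as.numeric(u_phi), log(lat))
}

# ---- the sampler ----------------------------------------------------------

run_filtered_chain <- function(model, y, rt_s, mask, hyper, config, chain_id) {
  restart <- 0L
  repeat {
    seed <- config$seed + chain_id + 1000L * restart
    set.seed(seed)
    out <- try(run_filtered_chain_once(model, y, rt_s, mask, hyper, config,
                                       chain_id), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    restart <- restart + 1L
    if (restart > 5L) {
      stop("chain ", chain_id, " failed repeatedly: ",
           attr(out, "condition")$message, call. = FALSE)
    }
    message("chain ", chain_id, " diverged; restarting with a new seed (",
            restart, ")")
  }
}

run_filtered_chain_once <- function(model, y, rt_s, mask, hyper, config,
                                    chain_id) {
  K <- if (model == "markov") 4L else hyper$k_max
  eps0 <- stats::runif(1, 0.02, 0.2)
  theta <- draw_initial_theta(hyper, model, eps0)
  fn0 <- function(th) lp_grad_filtered(th, y, rt_s, mask, hyper, eps0, model)
  tries <- 0L
  while (!is.finite(fn0(theta)$lp) && tries < 50L) {
    theta <- draw_initial_theta(hyper, model, eps0)
    tries <- tries + 1L
  }
  if (!is.finite(fn0(theta)$lp)) {
    stop("could not initialize chain in a region of finite density")
  }

  make_target <- function(outer) {
    eps_slice <- if (model == "ct" && outer > 1L) stats::runif(1, 0.02, 0.2)
                 else eps0
    list(fn = function(th)
           lp_grad_filtered(th, y, rt_s, mask, hyper, eps_slice, model),
         tag = eps_slice)
  }
  record <- function(th, lp, outer, eps_slice) {
    par <- theta_to_params(th, K, if (model == "markov") diag(4) else NULL)
    hmm <- hmm_params(par$transition, par$emission)
    occ <- occupied_states(hmm, y, if (model == "ct") eps_slice else 0)
    posterior_sample(hmm, par$later,
                     slice_eps = if (model == "ct") eps_slice else NA_real_,
                     chain = chain_id, step = outer, lp = lp, occupied = occ)
  }
  nuts_chain(make_target, theta, config$n_outer_steps, config$n_inner_steps,
             record, max_depth = config$max_tree_depth)
}

# number of states carrying appreciable time-averaged belief mass
occupied_states <- function(hmm, y, eps, threshold = 0.01) {
  res <- filter_hmm_cpp(hmm$transition, hmm$emission, as.integer(y),
                        as.numeric(stationary_belief(hmm$transition)), eps)
  sum(colMeans(res$beliefs) > threshold)
}

prepare_train_data <- function(seq, trials, config) {
  tr <- if (is.null(trials)) as.data.frame(seq) else trials
  keep <- tr$block %in% config$train_blocks
  if (!any(keep)) {
    # fall back to all blocks when the configured train set is absent
    keep <- rep(TRUE, nrow(tr))
  }
  tr <- tr[keep, , drop = FALSE]
  mask <- valid_trial_mask(tr, config)
  if (!any(mask)) stop("no valid trials in the training blocks", call. = FALSE)
  list(y = as.integer(tr$stimulus), rt_s = ifelse(is.na(tr$rt_ms), 0, tr$rt_ms) / 1000,
       mask = mask, trials = tr)
}

new_ct_fit <- function(samples, model, config, hyper, fixed_hmm = NULL) {
  structure(list(samples = samples, model = model, config = config,
                 hyper = hyper, fixed_hmm = fixed_hmm),
            class = "ct_fit")
}

#' @export
print.ct_fit <- function(x, ...) {
  cat(sprintf("ct_fit [%s]: %d samples, %d chains (%s preset)\n", x$model,
              length(x$samples),
              length(unique(vapply(x$samples, `[[`, 1L, "chain"))),
              x$config$preset))
  invisible(x)
}

#' Fit the full Cognitive Tomography model
#'
#' Samples the joint posterior over the internal HMM (up to `k_max` states)
#' and the LATER parameters from the training blocks of a trial table. Each
#' outer step resamples the slicing variable and takes `n_inner_steps` NUTS
#' updates of all continuous parameters; the first half of each chain is
#' the adaptation phase.
#'
#' @param seq an `asrt_sequence`, or `NULL` to take stimuli from `trials`.
#' @param trials trial table with `block`, `stimulus`, `trial_type`,
#'   `correct`, `rt_ms`; restricted internally to `config$train_blocks`
#'   (all blocks if none of them are present).
#' @param hyper an [hdp_hyper()].
#' @param config a [fit_config()].
#' @return A `ct_fit`: list of [posterior_sample()]s plus the configuration.
#' @export
fit_ct <- function(seq = NULL, trials = NULL, hyper = hdp_hyper(),
                   config = fit_config()) {
  dat <- prepare_train_data(seq, trials, config)
  samples <- list()
  for (chain in seq_len(config$n_chains)) {
    samples <- c(samples,
                 run_filtered_chain("ct", dat$y, dat$rt_s, dat$mask, hyper,
                                    config, chain))
  }
  new_ct_fit(samples, "ct", config, hyper)
}

#' Fit the observation-level Markov model
#'
#' Four states in one-to-one correspondence with the stimuli (identity
#' emissions); the transition rows carry a `Dirichlet(alpha0/4, ...)` prior
#' and are sampled jointly with the LATER parameters by NUTS.
#'
#' @inheritParams fit_ct
#' @return A `ct_fit` with `model = "markov"`.
#' @export
fit_markov <- function(seq = NULL, trials = NULL, hyper = hdp_hyper(),
                       config = fit_config()) {
  dat <- prepare_train_data(seq, trials, config)
  samples <- list()
  for (chain in seq_len(config$n_chains)) {
    samples <- c(samples,
                 run_filtered_chain("markov", dat$y, dat$rt_s, dat$mask,
                                    hyper, config, chain))
  }
  new_ct_fit(samples, "markov", config, hyper)
}

#' Calibrate the LATER parameters of a fixed internal model
#'
#' Freezes `pi` and `phi` (e.g. the ideal observer) and samples only the
#' response-time parameters; the per-trial predictive probabilities are
#' computed once from the frozen model.
#'
#' @param hmm the frozen internal model, an [hmm_params()].
#' @inheritParams fit_ct
#' @return A `ct_fit` with `model = "fixed"`; every sample carries the
#'   frozen model untouched.
#' @export
fit_fixed_model <- function(hmm, seq = NULL, trials = NULL,
                            hyper = hdp_hyper(), config = fit_config()) {
  stopifnot(inherits(hmm, "hmm_params"))
  dat <- prepare_train_data(seq, trials, config)
  preds <- sequence_predictions(hmm, dat$y)
  p_all <- pmin(pmax(preds[cbind(seq_along(dat$y), dat$y)], P_FLOOR), 1 - 1e-9)
  p <- p_all[dat$mask]
  rt <- dat$rt_s[dat$mask]
  rp <- hyper$rt_priors
  shapes <- c(rp$theta0[1], rp$mu[1], rp$sigma[1])
  rates <- c(rp$theta0[2], rp$mu[2], rp$sigma[2])

  fn <- function(v) {
    lat <- exp(v)
    g <- later_loglik_grad(rt, p, lat[1], lat[2], lat[3])
    if (!is.finite(g$lp)) return(list(lp = -Inf, grad = 0 * v))
    list(lp = g$lp + sum(gamma_exp_lp(v, shapes, rates)),
         grad = g$grad * lat + gamma_exp_grad(v, shapes, rates))
  }

  draw_v <- function() {
    lat <- pmin(pmax(c(stats::rgamma(1, shapes[1], rates[1]),
                       stats::rgamma(1, shapes[2], rates[2]),
                       stats::rgamma(1, shapes[3], rates[3])),
                     c(0.01, 1, 0.2)), c(0.5, 40, 20))
    # the offset must start below the fastest valid response time
    lat[1] <- min(lat[1], 0.8 * min(rt))
    log(lat)
  }
  samples <- list()
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain)
    v <- draw_v()
    tries <- 0L
    while (!is.finite(fn(v)$lp) && tries < 50L) {
      v <- draw_v()
      tries <- tries + 1L
    }
    record <- function(th, lp, outer, tag) {
      lat <- exp(th)
      posterior_sample(hmm, later_params(lat[1], lat[2], lat[3]), NA_real_,
                       chain, outer, lp = lp)
    }
    samples <- c(samples,
                 nuts_chain(function(outer) list(fn = fn, tag = NULL), v,
                            config$n_outer_steps, config$n_inner_steps,
                            record, max_depth = config$max_tree_depth))
  }
  new_ct_fit(samples, "fixed", config, hyper, fixed_hmm = hmm)
}

# vectorized LATER log likelihood and gradient in (theta0, mu, sigma)
later_loglik_grad <- function(rt, p, theta0, mu, sigma) {
  d <- rt - theta0
  if (any(d <= 0)) return(list(lp = -Inf, grad = c(0, 0, 0)))
  x <- -log(p)
  m <- mu / sigma
  z <- (x / d - mu) / sigma
  lam <- exp(stats::dnorm(m, log = TRUE) - stats::pnorm(m, log.p = TRUE))
  lp <- sum(stats::dnorm(z, log = TRUE) - log(sigma) -
              stats::pnorm(m, log.p = TRUE) + log(x) - 2 * log(d))
  n <- length(rt)
  g_theta0 <- sum(2 / d - z * x / (sigma * d^2))
  g_mu <- sum(z) / sigma - n * lam / sigma
  g_sigma <- sum(z^2 - 1) / sigma + n * lam * mu / sigma^2
  list(lp = lp, grad = c(g_theta0, g_mu, g_sigma))
}

# ---- prediction and diagnostics -------------------------------------------

#' Retained prediction samples
#'
#' The last `n_prediction_samples_per_chain` unique samples of each chain
#' (consecutive identical draws collapse).
#'
#' @param fit a `ct_fit`.
#' @return List of [posterior_sample()]s.
#' @export
retained_samples <- function(fit) {
  chains <- vapply(fit$samples, `[[`, 1L, "chain")
  out <- list()
  for (ch in unique(chains)) {
    sams <- fit$samples[chains == ch]
    keys <- vapply(sams, function(s) {
      paste(signif(c(s$hmm$transition[1, ], s$later$theta0, s$later$mu,
                     s$later$sigma), 12), collapse = ",")
    }, "")
    keep <- !duplicated(keys, fromLast = TRUE)
    sams <- sams[keep]
    n <- length(sams)
    take <- seq.int(max(1L, n - fit$config$n_prediction_samples_per_chain + 1L), n)
    out <- c(out, sams[take])
  }
  out
}

#' Predict response times for a stimulus sequence
#'
#' For each retained posterior sample, filters the full sequence (beliefs
#' are driven by stimuli only, never by the measured response times),
#' computes the per-trial point prediction [map_rt()] at the subjective
#' probability of the realized stimulus, and averages across samples.
#'
#' @param fit a `ct_fit`.
#' @param seq an `asrt_sequence` (typically the held-out test blocks).
#' @param config unused; kept for interface symmetry.
#' @return Numeric vector of predicted response times in seconds, one per
#'   trial of `seq`.
#' @export
predict_rts <- function(fit, seq, config = fit$config) {
  sams <- retained_samples(fit)
  y <- stimuli_of(seq)
  acc <- numeric(length(y))
  for (s in sams) {
    preds <- sequence_predictions(s$hmm, y)
    p <- preds[cbind(seq_along(y), y)]
    acc <- acc + map_rt(pmin(pmax(p, P_FLOOR), 1), s$later)
  }
  acc / length(sams)
}

#' Posterior-mean predictive probabilities
#'
#' Mean across retained samples of the full 4-vector of next-stimulus
#' probabilities at every trial of `seq`.
#'
#' @inheritParams predict_rts
#' @return A `T x 4` matrix of probabilities (rows sum to 1).
#' @export
predict_probs <- function(fit, seq) {
  sams <- retained_samples(fit)
  y <- stimuli_of(seq)
  acc <- matrix(0, length(y), 4)
  for (s in sams) acc <- acc + sequence_predictions(s$hmm, y)
  acc / length(sams)
}

#' Convergence diagnostics
#'
#' Per-chain means and central 90% intervals of the LATER parameters over
#' the second half of each chain, cross-chain agreement (largest
#' between-chain difference of means relative to the pooled posterior sd),
#' and the histogram of occupied-state counts.
#'
#' @param fit a `ct_fit` with at least 2 chains.
#' @param agreement_ratio flag chains as agreeing when all mean differences
#'   are below this multiple of the pooled sd.
#' @return List with `per_chain` (data.frame), `cross_chain` (data.frame
#'   with `max_mean_diff`, `pooled_sd`, `ratio`, `ok` per parameter), and
#'   `occupied` (table of occupied-state counts).
#' @export
diagnostics <- function(fit, agreement_ratio = 0.5) {
  chains <- vapply(fit$samples, `[[`, 1L, "chain")
  if (length(unique(chains)) < 2L) {
    stop("diagnostics require at least 2 chains", call. = FALSE)
  }
  steps <- vapply(fit$samples, `[[`, 1L, "step")
  half <- steps > max(steps) / 2
  pars <- c("theta0", "mu", "sigma")
  rows <- list()
  for (ch in unique(chains)) {
    sams <- fit$samples[chains == ch & half]
    for (p in pars) {
      v <- vapply(sams, function(s) s$later[[p]], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, parameter = p, mean = mean(v), sd = stats::sd(v),
        q05 = stats::quantile(v, 0.05, names = FALSE),
        q95 = stats::quantile(v, 0.95, names = FALSE))
    }
  }
  per_chain <- do.call(rbind, rows)
  cross <- do.call(rbind, lapply(pars, function(p) {
    sub <- per_chain[per_chain$parameter == p, ]
    all_v <- vapply(fit$samples[half], function(s) s$later[[p]], 0)
    pooled <- stats::sd(all_v)
    md <- max(dist(sub$mean))
    data.frame(parameter = p, max_mean_diff = md, pooled_sd = pooled,
               ratio = if (pooled > 0) md / pooled else 0,
               ok = pooled == 0 || md / pooled < agreement_ratio)
  }))
  occ <- vapply(fit$samples[half], `[[`, 1L, "occupied")
  list(per_chain = per_chain, cross_chain = cross,
       occupied = table(occ[!is.na(occ)]))
}

#' Fit an internal model to stimulus statistics alone
#'
#' Samples the truncated-HDP HMM posterior given only a stimulus sequence
#' (the predictive likelihood of the stimuli, no response times). This is
#' how ground-truth internal models representing different amounts of
#' exposure are derived in the synthetic validation harness.
#'
#' @param y stimulus vector or `asrt_sequence`.
#' @param hyper an [hdp_hyper()].
#' @param config a [fit_config()] (chain schedule reused).
#' @return A `ct_fit` with `model = "stimulus"`; the `later` slot of each
#'   sample is a placeholder.
#' @export
fit_stimulus_model <- function(y, hyper = hdp_hyper(), config = fit_config()) {
  y <- stimuli_of(y)
  K <- hyper$k_max
  dummy_rt <- numeric(length(y))
  dummy_mask <- integer(length(y))
  samples <- list()
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain)
    eps0 <- stats::runif(1, 0.02, 0.2)
    theta <- draw_initial_theta(hyper, "stimulus", eps0)
    make_target <- function(outer) {
      eps_slice <- if (outer > 1L) stats::runif(1, 0.02, 0.2) else eps0
      list(fn = function(th)
             lp_grad_filtered(th, y, dummy_rt, dummy_mask, hyper, eps_slice,
                              "stimulus"),
           tag = eps_slice)
    }
    record <- function(th, lp, outer, eps_slice) {
      n_pi <- K * (K - 1L)
      pi_m <- t(apply(matrix(th[seq_len(n_pi)], K, K - 1L), 1, softmax_row))
      phi_m <- t(apply(matrix(th[n_pi + seq_len(K * 3L)], K, 3L), 1,
                       softmax_row))
      posterior_sample(hmm_params(pi_m, phi_m), later_params(0.1, 8, 2),
                       eps_slice, chain, outer, lp = lp,
                       occupied = occupied_states(hmm_params(pi_m, phi_m), y,
                                                  eps_slice))
    }
    samples <- c(samples,
                 nuts_chain(make_target, theta, config$n_outer_steps,
                            config$n_inner_steps, record,
                            max_depth = config$max_tree_depth))
  }
  new_ct_fit(samples, "stimulus", config, hyper)
}
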