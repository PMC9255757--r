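make_small_dataset <- function(n_blocks = 4, seed = 7) {
  pat <- default_pattern()
  seqn <- generate_session(pat, n_blocks = n_blocks, seed = seed)
  sp <- markov_participant(seed + 1)
  trl <- simulate_participant(sp, seqn, seed = seed + 2)
  list(pattern = pat, seq = seqn, sp = sp, trials = trl)
}

test_that("the valid-trial mask applies the exclusion rules", {
  cfg <- fit_config()
  tr <- data.frame(trial_type = c(rep("warmup", 5), rep(c("pattern", "random"), 5)),
                   correct = 1L, rt_ms = 400)
  m <- valid_trial_mask(tr, cfg)
  expect_equal(sum(!m), 5)
  expect_true(all(which(!m) == 1:5))

  # handcrafted 10-trial table: one incorrect, one fast trial
  tr10 <- data.frame(trial_type = c("warmup", rep("pattern", 9)),
                     correct = c(1, 1, 0, 1, 1, 1, 1, 1, 1, 1),
                     rt_ms = c(400, 400, 400, 150, 400, 400, 400, 400, 400, 400))
  expect_equal(sum(valid_trial_mask(tr10, cfg)), 7)

  expect_warning(
    valid_trial_mask(transform(tr10, correct = 0), cfg), "no valid trials")
  expect_error(valid_trial_mask(data.frame(rt_ms = 1), cfg), "lacks columns")
})

test_that("log joint is additive in the data and matches per-trial densities", {
  d <- make_small_dataset()
  cfg <- fit_config(train_blocks = 1:4, test_blocks = 5:6)
  hyper <- hdp_hyper(k_max = 5)
  set.seed(1)
  hmm <- random_hmm(5)
  lat <- later_params(0.17, 7, 1.5)
  smp <- posterior_sample(hmm, lat, slice_eps = NA_real_)

  # likelihood term equals the sum of independent per-trial density logs
  lik <- cogtomo:::rt_loglik(smp, d$seq, d$trials, cfg)
  preds <- sequence_predictions(hmm, d$seq)
  p <- preds[cbind(seq_len(nrow(d$trials)), d$trials$stimulus)]
  mask <- valid_trial_mask(d$trials, cfg)
  by_hand <- sum(rt_density(d$trials$rt_ms[mask] / 1000,
                            pmin(pmax(p[mask], cogtomo:::P_FLOOR), 1 - 1e-9),
                            lat, log = TRUE))
  expect_equal(lik, by_hand, tolerance = 1e-10)

  # doubling the dataset doubles the likelihood term
  seq2 <- d$seq
  seq2$trials <- rbind(d$seq$trials, d$seq$trials)
  trials2 <- rbind(d$trials, d$trials)
  lik2 <- cogtomo:::rt_loglik(smp, seq2, trials2, cfg)
  # (filtering re-enters the second copy with a carried belief, so restrict
  # the check to a single-state model where the belief is irrelevant)
  one <- hmm_params(matrix(1, 1, 1), matrix(c(0.2, 0.3, 0.4, 0.1), 1))
  s1 <- posterior_sample(one, lat)
  expect_equal(cogtomo:::rt_loglik(s1, seq2, trials2, cfg),
               2 * cogtomo:::rt_loglik(s1, d$seq, d$trials, cfg),
               tolerance = 1e-8)

  # prior terms match reference Dirichlet/Gamma log-densities
  lj <- log_joint(smp, d$seq, d$trials, hyper, cfg)
  a_pi <- rep(hyper$alpha0 / 5, 5)
  ref_dir <- function(x, a) {
    sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
  }
  prior_ref <- sum(apply(hmm$transition, 1, ref_dir, a = a_pi)) +
    sum(apply(hmm$emission, 1, ref_dir, a = hyper$emission_base)) +
    stats::dgamma(lat$theta0, 1, 10, log = TRUE) +
    stats::dgamma(lat$mu, 1, 0.1, log = TRUE) +
    stats::dgamma(lat$sigma, 1, 0.01, log = TRUE)
  expect_equal(lj, prior_ref + lik, tolerance = 1e-8)
})

test_that("the unconstrained sampler target equals log joint plus Jacobians", {
  d <- make_small_dataset()
  cfg <- fit_config(train_blocks = 1:4, test_blocks = 5:6)
  hyper <- hdp_hyper(k_max = 4)
  set.seed(2)
  eps <- 0.1
  theta <- cogtomo:::draw_initial_theta(hyper, "ct", eps)
  par <- cogtomo:::theta_to_params(theta, 4)
  smp <- posterior_sample(hmm_params(par$transition, par$emission),
                          par$later, eps)
  dat <- cogtomo:::prepare_train_data(d$seq, d$trials, cfg)
  lp_cpp <- cogtomo:::lp_grad_filtered(theta, dat$y, dat$rt_s, dat$mask,
                                       hyper, eps, "ct")$lp
  jac <- sum(log(par$transition)) + sum(log(par$emission)) +
    sum(log(c(par$later$theta0, par$later$mu, par$later$sigma)))
  expect_equal(log_joint(smp, dat$y, dat$trials, hyper, cfg) + jac, lp_cpp,
               tolerance = 1e-8)
})

test_that("the sampler gradient matches finite differences", {
  d <- make_small_dataset(n_blocks = 2)
  cfg <- fit_config(train_blocks = 1:2, test_blocks = 3:4)
  hyper <- hdp_hyper(k_max = 4)
  dat <- cogtomo:::prepare_train_data(d$seq, d$trials, cfg)
  lgf <- cogtomo:::lp_grad_filtered
  set.seed(3)
  for (model in c("markov", "ct")) {
    # eps = 0 keeps the target smooth (no truncation-set changes under
    # perturbation); the initial stationary belief is held fixed by
    # evaluating gradients away from sensitivity (checked loosely for ct)
    eps <- if (model == "ct") 0.0001 else NA
    theta <- cogtomo:::draw_initial_theta(hyper, model, 0.1)
    ev <- lgf(theta, dat$y, dat$rt_s, dat$mask, hyper, eps, model)
    idx <- sample(length(theta), 6)
    fd <- vapply(idx, function(i) {
      h <- 1e-6
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (lgf(tp, dat$y, dat$rt_s, dat$mask, hyper, eps, model)$lp -
         lgf(tm, dat$y, dat$rt_s, dat$mask, hyper, eps, model)$lp) / (2 * h)
    }, 0)
    tol <- if (model == "markov") 1e-4 else 0.02
    expect_lt(max(abs(fd - ev$grad[idx]) / (abs(fd) + 1)), tol)
  }
})

test_that("log joint is continuous in the response-time parameters", {
  d <- make_small_dataset()
  cfg <- fit_config(train_blocks = 1:4, test_blocks = 5:6)
  hmm <- markov_participant(5)$internal_model
  base <- c(0.15, 7, 1.5)
  lj <- function(v) {
    log_joint(posterior_sample(hmm, later_params(v[1], v[2], v[3])),
              d$seq, d$trials, hdp_hyper(), cfg)
  }
  for (i in 1:3) {
    h <- 1e-5 * base[i]
    up <- base; up[i] <- up[i] + h
    expect_lt(abs(lj(up) - lj(base)), 1)  # small parameter step, small change
  }
})

test_that("short chains return well-formed fits with valid samples", {
  d <- make_small_dataset(n_blocks = 3)
  cfg <- fit_config(n_chains = 2, n_outer_steps = 2, n_inner_steps = 2,
                    train_blocks = 1:3, test_blocks = 4:5, seed = 5)
  hyper <- hdp_hyper(k_max = 5)
  for (ffun in list(fit_ct, fit_markov)) {
    fit <- ffun(d$seq, d$trials, hyper, cfg)
    expect_s3_class(fit, "ct_fit")
    expect_length(fit$samples, 4)
    for (s in fit$samples) {
      expect_equal(rowSums(s$hmm$transition), rep(1, s$hmm$n_states),
                   tolerance = 1e-8)
      expect_equal(rowSums(s$hmm$emission), rep(1, s$hmm$n_states),
                   tolerance = 1e-8)
      expect_true(s$later$mu > 0 && s$later$sigma > 0 && s$later$theta0 >= 0)
      if (!is.na(s$slice_eps)) {
        expect_true(s$slice_eps >= 0.02 && s$slice_eps <= 0.2)
      }
    }
  }
  fit3 <- fit_stimulus_model(d$seq, hyper, cfg)
  expect_length(fit3$samples, 4)
  expect_error(suppressWarnings(
    fit_ct(d$seq, transform(d$trials, correct = 0), hyper, cfg)))
})

test_that("fixed-model fits freeze the internal model and calibrate LATER", {
  pat <- default_pattern()
  seqn <- generate_session(pat, n_blocks = 8, seed = 31)
  io_soft <- cogtomo:::soften_hmm(ideal_observer(pat), 0.05, 0.08)
  truth <- later_params(0.18, 8, 2)
  sp <- synthetic_participant(io_soft, truth)
  trl <- simulate_participant(sp, seqn, seed = 32)
  cfg <- fit_config("desk", train_blocks = 1:8, test_blocks = integer(0),
                    seed = 33)
  fit <- fit_fixed_model(io_soft, seqn, trl, config = cfg)
  # frozen model untouched in every sample
  expect_true(all(vapply(fit$samples, function(s)
    identical(s$hmm, io_soft), TRUE)))
  # posterior concentrates near the generating parameters
  sams <- retained_samples(fit)
  post <- vapply(sams, function(s)
    c(s$later$theta0, s$later$mu, s$later$sigma), numeric(3))
  expect_lt(abs(mean(post[1, ]) - truth$theta0), 0.02)
  expect_lt(abs(mean(post[2, ]) - truth$mu) / truth$mu, 0.15)
  expect_lt(abs(mean(post[3, ]) - truth$sigma) / truth$sigma, 0.3)
})

test_that("predictions average retained samples and ignore measured RTs", {
  d <- make_small_dataset(n_blocks = 3)
  cfg <- fit_config(n_chains = 2, n_outer_steps = 4, n_inner_steps = 2,
                    n_prediction_samples_per_chain = 2,
                    train_blocks = 1:3, test_blocks = 4:5, seed = 6)
  fit <- fit_markov(d$seq, d$trials, config = cfg)
  sams <- retained_samples(fit)
  expect_lte(length(sams), 4)
  y <- d$seq$trials$stimulus
  manual <- rowMeans(vapply(sams, function(s) {
    p <- sequence_predictions(s$hmm, y)[cbind(seq_along(y), y)]
    map_rt(pmin(pmax(p, cogtomo:::P_FLOOR), 1), s$later)
  }, numeric(length(y))))
  expect_equal(predict_rts(fit, d$seq), manual, tolerance = 1e-12)

  # single-sample fit: predictions equal that sample's map_rt sequence
  fit1 <- fit
  fit1$samples <- fit$samples[1]
  fit1$config$n_prediction_samples_per_chain <- 1L
  s1 <- fit$samples[[1]]
  p1 <- sequence_predictions(s1$hmm, y)[cbind(seq_along(y), y)]
  expect_equal(predict_rts(fit1, d$seq),
               map_rt(pmin(pmax(p1, cogtomo:::P_FLOOR), 1), s1$later))
})

test_that("diagnostics summarize chains and reject single-chain fits", {
  d <- make_small_dataset(n_blocks = 3)
  cfg <- fit_config(n_chains = 2, n_outer_steps = 6, n_inner_steps = 2,
                    train_blocks = 1:3, test_blocks = 4:5, seed = 6)
  fit <- fit_markov(d$seq, d$trials, config = cfg)
  dg <- diagnostics(fit)
  expect_setequal(unique(dg$per_chain$parameter), c("theta0", "mu", "sigma"))
  expect_equal(nrow(dg$cross_chain), 3)

  # identical chains -> zero discrepancy
  fit_dup <- fit
  fit_dup$samples <- c(fit$samples[1:3],
                       lapply(fit$samples[1:3], function(s) {
                         s$chain <- 2L
                         s
                       }))
  dg2 <- diagnostics(fit_dup)
  expect_true(all(dg2$cross_chain$max_mean_diff == 0))

  fit1 <- fit
  fit1$samples <- fit$samples[vapply(fit$samples, `[[`, 1L, "chain") == 1]
  expect_error(diagnostics(fit1), "2 chains")
})

test_that("fit serialization round-trips through JSON-lines", {
  d <- make_small_dataset(n_blocks = 3)
  cfg <- fit_config(n_chains = 2, n_outer_steps = 2, n_inner_steps = 1,
                    train_blocks = 1:3, test_blocks = 4:5, seed = 8)
  fit <- fit_ct(d$seq, d$trials, hdp_hyper(k_max = 4), cfg)
  path <- tempfile(fileext = ".jsonl")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$model, "ct")
  expect_length(back$samples, length(fit$samples))
  expect_equal(back$samples[[3]]$hmm$transition,
               fit$samples[[3]]$hmm$transition, tolerance = 1e-12)
  expect_equal(back$samples[[2]]$later$mu, fit$samples[[2]]$later$mu,
               tolerance = 1e-12)
  expect_equal(back$config$train_blocks, cfg$train_blocks)
  unlink(path)
})

test_that("prediction performance saturates in the number of retained samples", {
  pat <- default_pattern()
  seqn <- generate_session(pat, n_blocks = 20, seed = 41)
  sp <- markov_participant(seed = 42)
  trl <- simulate_participant(sp, seqn, seed = 43)
  cfg <- fit_config("desk", n_outer_steps = 260, seed = 44)
  fit <- fit_markov(seqn, trl, config = cfg)
  test_seq <- subset_blocks(seqn, cfg$test_blocks)
  mask <- valid_trial_mask(trl[trl$block %in% cfg$test_blocks, ], cfg)
  obs <- trl$rt_ms[trl$block %in% cfg$test_blocks][mask] / 1000
  r2_at <- vapply(c(60L, 120L), function(n) {
    f <- fit
    f$config$n_prediction_samples_per_chain <- n
    r2_score(predict_rts(f, test_seq)[mask], obs)
  }, 0)
  expect_lt(abs(r2_at[1] - r2_at[2]), 0.01)
})
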