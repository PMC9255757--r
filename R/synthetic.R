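#' Synthetic participants and the validation harness
#'
#' A synthetic participant is an internal HMM plus LATER parameters; their
#' response times are generated exactly as the behavioural model assumes
#' (filter the stimuli, read off the subjective probability of the realized
#' stimulus, draw the response time through the LATER model). The harness
#' crosses three ground-truth internal models of increasing structural
#' knowledge with a 3 x 3 x 3 grid of response-time parameters, yielding the
#' 81 datasets used to validate the inference machinery by parameter and
#' subjective-probability recovery.
#'
#' @name synthetic
NULL

#' Construct a synthetic participant
#'
#' @param internal_model an [hmm_params()].
#' @param later a [later_params()].
#' @param label one of `early`, `middle`, `late`, `custom`.
#' @return Object of class `synthetic_participant`.
#' @export
synthetic_participant <- function(internal_model, later, label = "custom") {
  stopifnot(inherits(internal_model, "hmm_params"),
            inherits(later, "later_params"))
  label <- match.arg(label, c("early", "middle", "late", "custom"))
  structure(list(internal_model = internal_model, later = later,
                 label = label),
            class = "synthetic_participant")
}

#' Soften a deterministic HMM
#'
#' Mixes every transition and emission row with the uniform distribution.
#' Deterministic models (one-hot emissions, e.g. the exact ideal observer)
#' assign probability zero to stimuli that contradict the alternating
#' structure, which genuinely happens on warm-up trials; a small floor makes
#' them usable as filtering models on full ASRT sessions.
#'
#' @param hmm an [hmm_params()].
#' @param transition_noise,emission_noise mixing weights in `[0, 1)`.
#' @return A strictly positive [hmm_params()].
#' @export
soften_hmm <- function(hmm, transition_noise, emission_noise) {
  K <- hmm$n_states
  tr <- (1 - transition_noise) * hmm$transition + transition_noise / K
  em <- (1 - emission_noise) * hmm$emission + emission_noise / 4
  hmm_params(tr, em)
}

#' Ground-truth internal models at three levels of experience
#'
#' Returns `early`, `middle` and `late` internal models emulating
#' participants with increasing exposure to the ASRT statistics:
#' \describe{
#'   \item{early}{a near-Markov 4-state model (identity-like emissions,
#'     mildly structured transitions) — the inductive bias that dominates
#'     before the alternating structure is learned;}
#'   \item{middle}{the 8-state true-process skeleton with heavily softened
#'     emissions and transitions — partial knowledge of the pattern;}
#'   \item{late}{the ideal observer with lightly softened parameters —
#'     near-complete knowledge.}
#' }
#' With `mode = "stimulus_fit"` the models are instead posterior draws from
#' [fit_stimulus_model()] on ASRT stimulus streams of `trials_per_level`
#' trials, emulating learning by exposure.
#'
#' @param pattern an [asrt_pattern].
#' @param seed integer seed.
#' @param mode `"constructed"` (default, deterministic) or `"stimulus_fit"`.
#' @param trials_per_level exposure lengths for `stimulus_fit` mode.
#' @param config sampling schedule for `stimulus_fit` mode.
#' @return Named list of three [hmm_params()]: `early`, `middle`, `late`,
#'   ordered by decreasing KL divergence from the ideal-observer
#'   predictions.
#' @export
make_ground_truth_models <- function(pattern = asrt_pattern(c(2, 4, 3, 1)),
                                     seed = 1L,
                                     mode = c("constructed", "stimulus_fit"),
                                     trials_per_level = c(640L, 1280L, 2400L),
                                     config = fit_config()) {
  mode <- match.arg(mode)
  if (mode == "constructed") {
    set.seed(seed)
    # early: near-Markov; transitions mildly biased away from uniform
    bias <- matrix(stats::runif(16, 0, 1), 4, 4)
    tr4 <- 0.75 * matrix(0.25, 4, 4) + 0.25 * bias / rowSums(bias)
    tr4 <- tr4 / rowSums(tr4)
    early <- hmm_params(tr4, 0.9 * diag(4) + 0.025)
    io <- ideal_observer(pattern)
    middle <- soften_hmm(io, 0.35, 0.45)
    late <- soften_hmm(io, 0.05, 0.08)
    return(list(early = early, middle = middle, late = late))
  }
  models <- list()
  levels <- c("early", "middle", "late")
  for (i in seq_along(trials_per_level)) {
    n_tr <- trials_per_level[i]
    n_blocks <- ceiling(n_tr / 85)
    seq_i <- generate_session(pattern, n_blocks = n_blocks,
                              seed = seed + i)
    y <- stimuli_of(seq_i)[seq_len(n_tr)]
    cfg <- config
    cfg$seed <- seed + 10L * i
    fit <- fit_stimulus_model(y, hyper = hdp_hyper(), config = cfg)
    best <- which.max(vapply(fit$samples, `[[`, 0, "lp"))
    models[[levels[i]]] <- fit$samples[[best]]$hmm
  }
  models
}

#' Simulate a synthetic participant's session
#'
#' Filters the stimulus sequence under the participant's internal model and
#' draws each response time from the LATER model at the subjective
#' probability of the actually realized stimulus. All trials are correct
#' unless an error rule is supplied: with `error_rate > 0`, a trial is
#' answered incorrectly with probability `error_rate * (1 - p)` (harder
#' trials fail more often) and the erroneous key is drawn from the
#' participant's own prediction over the remaining stimuli.
#'
#' @param sp a [synthetic_participant()].
#' @param seq an `asrt_sequence`.
#' @param seed integer seed.
#' @param error_rate scale of the probability-dependent error rule
#'   (default 0: all trials correct, as in the validation harness).
#' @param participant_id id recorded in the table.
#' @param session session number recorded in the table.
#' @return A trial table: the sequence's columns plus `participant_id`,
#'   `session`, `response`, `correct`, `rt_ms`.
#' @export
simulate_participant <- function(sp, seq, seed = NULL, error_rate = 0,
                                 participant_id = "synthetic", session = 1L) {
  stopifnot(inherits(sp, "synthetic_participant"),
            inherits(seq, "asrt_sequence"))
  if (!is.null(seed)) set.seed(seed)
  y <- stimuli_of(seq)
  preds <- sequence_predictions(sp$internal_model, y)
  p <- preds[cbind(seq_along(y), y)]
  p <- pmin(pmax(p, P_FLOOR), 1)
  rt_s <- sample_rt(p, sp$later)
  tr <- as.data.frame(seq)
  tr$participant_id <- participant_id
  tr$session <- as.integer(session)
  tr$response <- y
  tr$correct <- 1L
  if (error_rate > 0) {
    err <- stats::runif(length(y)) < error_rate * (1 - p)
    for (t in which(err)) {
      w <- preds[t, ]
      w[y[t]] <- 0
      tr$response[t] <- sample(1:4, 1, prob = w / sum(w))
    }
    tr$correct[err] <- 0L
  }
  tr$rt_ms <- rt_s * 1000
  tr[, c("participant_id", "session", "block", "trial", "trial_global",
         "stimulus", "trial_type", "pattern_phase", "response", "correct",
         "rt_ms")]
}

#' Build the validation grid of synthetic datasets
#'
#' Crosses each ground-truth internal model with every combination of the
#' response-time parameter values (by default 3 values each for `theta0`,
#' `mu`, `sigma`, i.e. 27 cells per model and 81 datasets for three
#' models). Dataset ids encode the cell: `model.theta0_i.mu_j.sigma_k`.
#' The default values are chosen so the simulated response-time standard
#' deviations bracket the range typical of human ASRT sessions
#' (roughly 60-250 ms).
#'
#' @param models named list of [hmm_params()] ground-truth models.
#' @param theta0_values,mu_values,sigma_values parameter values (seconds and
#'   1/seconds).
#' @param seq the stimulus sequence to simulate (default 10 standard
#'   blocks).
#' @param seed integer seed; each dataset derives its own sub-seed.
#' @return List of datasets; each has `id`, `model_label`, `participant`
#'   (the generating [synthetic_participant()]), `trials` (simulated trial
#'   table), `p_true` (ground-truth subjective probabilities of the
#'   realized stimuli) and `rt_sd_ms`.
#' @export
validation_grid <- function(models = make_ground_truth_models(),
                            theta0_values = c(0.12, 0.18, 0.24),
                            mu_values = c(6, 8, 10),
                            sigma_values = c(1, 2, 3),
                            seq = NULL, seed = 1L) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  if (is.null(seq)) {
    seq <- generate_session(asrt_pattern(c(2, 4, 3, 1)), n_blocks = 10L,
                            seed = seed)
  }
  datasets <- list()
  idx <- 0L
  for (m in names(models)) {
    preds <- sequence_predictions(models[[m]], seq)
    y <- stimuli_of(seq)
    p_true <- pmin(pmax(preds[cbind(seq_along(y), y)], P_FLOOR), 1)
    for (i in seq_along(theta0_values)) {
      for (j in seq_along(mu_values)) {
        for (k in seq_along(sigma_values)) {
          idx <- idx + 1L
          lat <- later_params(theta0_values[i], mu_values[j], sigma_values[k])
          sp <- synthetic_participant(models[[m]], lat, "custom")
          tr <- simulate_participant(sp, seq, seed = seed + 131L * idx)
          datasets[[idx]] <- list(
            id = sprintf("%s.theta0_%d.mu_%d.sigma_%d", m, i, j, k),
            model_label = m, participant = sp, trials = tr,
            p_true = p_true, rt_sd_ms = stats::sd(tr$rt_ms))
        }
      }
    }
  }
  datasets
}

#' Recovery report over fitted validation datasets
#'
#' For each dataset/fit pair, computes on the held-out test blocks: the
#' response-time prediction performance of the fitted model, the
#' subjective-probability recovery (squared correlation of the inferred
#' mean predictive probability of the realized stimulus with the
#' ground-truth one), and the response-time performance of the generating
#' model itself as a ceiling reference.
#'
#' @param datasets list as from [validation_grid()].
#' @param fits list of `ct_fit`s aligned with `datasets`.
#' @param seq the stimulus sequence the datasets were simulated on.
#' @param config a [fit_config()] naming the test blocks.
#' @return data.frame with one row per dataset: `id`, `model_label`,
#'   `rt_sd_ms`, `rt_r2`, `prob_recovery_r2`, `rt_r2_ceiling`.
#' @export
recovery_report <- function(datasets, fits, seq, config = fit_config()) {
  stopifnot(length(datasets) == length(fits))
  test_seq <- subset_blocks(seq, config$test_blocks)
  test_idx <- which(seq$trials$block %in% config$test_blocks)
  y_test <- stimuli_of(test_seq)
  rows <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    fit <- fits[[i]]
    mask <- valid_trial_mask(ds$trials[test_idx, , drop = FALSE], config)
    rt_obs <- ds$trials$rt_ms[test_idx][mask] / 1000

    rt_hat <- predict_rts_of(fit, y_test)[mask]
    probs <- probs_of(fit, y_test)
    p_hat <- probs[cbind(seq_along(y_test), y_test)]
    p_true <- ds$p_true[test_idx]

    sp <- ds$participant
    preds0 <- sequence_predictions(sp$internal_model, y_test)
    p0 <- pmin(pmax(preds0[cbind(seq_along(y_test), y_test)], P_FLOOR), 1)
    rt_ceiling <- map_rt(p0, sp$later)[mask]

    data.frame(id = ds$id, model_label = ds$model_label,
               rt_sd_ms = ds$rt_sd_ms,
               rt_r2 = r2_score(rt_hat, rt_obs),
               prob_recovery_r2 = r2_score(p_hat, p_true),
               rt_r2_ceiling = r2_score(rt_ceiling, rt_obs))
  })
  do.call(rbind, rows)
}

# allow an oracle "fit" (a bare synthetic_participant or hmm) in place of a
# ct_fit, so perfect-recovery reference rows can be computed
predict_rts_of <- function(fit, y) {
  if (inherits(fit, "ct_fit")) return(predict_rts(fit, y))
  sp <- fit
  preds <- sequence_predictions(sp$internal_model, y)
  p <- pmin(pmax(preds[cbind(seq_along(y), y)], P_FLOOR), 1)
  map_rt(p, sp$later)
}

probs_of <- function(fit, y) {
  if (inherits(fit, "ct_fit")) return(predict_probs(fit, y))
  sequence_predictions(fit$internal_model, y)
}
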