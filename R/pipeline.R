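#' End-to-end pipeline
#'
#' Runs simulate -> fit (one or more models) -> predict -> evaluate on a
#' synthetic participant, writing every artifact with a provenance header.
#' All randomness derives from the single seed in the configuration:
#' stimulus generation uses `seed`, the participant simulation `seed + 1`,
#' and each fit's chains `seed + chain`.
#'
#' @param out_dir output directory (created if absent).
#' @param models character subset of `c("ct", "markov", "ideal", "trigram")`.
#' @param pattern an [asrt_pattern].
#' @param participant a [synthetic_participant()]; default: the `late`
#'   ground-truth model with mid-grid LATER parameters.
#' @param n_blocks blocks to simulate; must cover train and test blocks.
#' @param config a [fit_config()].
#' @param hyper an [hdp_hyper()].
#' @return Invisibly, a list with the evaluation table and the paths of
#'   the four artifact files (`trials`, `fits`, `predictions`, `metrics`).
#' @export
run_pipeline <- function(out_dir, models = c("ct", "markov"),
                         pattern = asrt_pattern(c(2, 4, 3, 1)),
                         participant = NULL, n_blocks = 20L,
                         config = fit_config(), hyper = hdp_hyper()) {
  models <- match.arg(models, c("ct", "markov", "ideal", "trigram"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- try({
    seqn <- generate_session(pattern, n_blocks = n_blocks, seed = config$seed)
    if (is.null(participant)) {
      gt <- make_ground_truth_models(pattern, seed = config$seed)
      participant <- synthetic_participant(gt$late,
                                           later_params(0.18, 8, 2), "late")
    }
    trials <- simulate_participant(participant, seqn, seed = config$seed + 1L)
    trials_path <- file.path(out_dir, "trials.tsv")
    write_trials(trials, trials_path, seed = config$seed, config = config)

    stage <- "fit"
    test_idx <- which(trials$block %in% config$test_blocks)
    test_seq <- subset_blocks(seqn, config$test_blocks)
    fit_paths <- character(0)
    preds <- list()
    for (m in models) {
      fit <- switch(m,
        ct = fit_ct(seqn, trials, hyper, config),
        markov = fit_markov(seqn, trials, hyper, config),
        # the evaluation copy of the ideal observer carries a small
        # probability floor: warm-up trials contradict its deterministic
        # alternation
        ideal = fit_fixed_model(soften_hmm(ideal_observer(pattern), 0.01, 0.02),
                                seqn, trials, hyper, config),
        trigram = NULL)
      if (!is.null(fit)) {
        fp <- file.path(out_dir, paste0("fit_", m, ".jsonl"))
        write_fit(fit, fp)
        fit_paths <- c(fit_paths, fp)
        preds[[m]] <- predict_rts(fit, test_seq)
      } else {
        tg <- trigram_predictions(test_seq, pattern)
        # calibrate a LATER map through the high/low probabilities with the
        # pooled valid response times (free slope/intercept enters via the
        # corr2 metric anyway)
        p <- tg$predictions[cbind(seq_len(nrow(tg$predictions)),
                                  test_seq$trials$stimulus)]
        preds[[m]] <- map_rt(p, later_params(0.18, 8, 2))
      }
    }

    stage <- "predict"
    pred_df <- data.frame(trial_global = trials$trial_global[test_idx])
    for (m in names(preds)) pred_df[[paste0("rt_pred_s_", m)]] <- preds[[m]]
    pred_path <- file.path(out_dir, "predictions.tsv")
    write_tsv(pred_df, pred_path, seed = config$seed, config = config)

    stage <- "evaluate"
    test_trials <- trials[test_idx, , drop = FALSE]
    metrics <- do.call(rbind, lapply(names(preds), function(m) {
      ev <- evaluate_rt_predictions(preds[[m]], test_trials, config)
      ev$model <- m
      ev
    }))
    metrics_path <- file.path(out_dir, "metrics.tsv")
    write_tsv(metrics, metrics_path, seed = config$seed, config = config)
    list(metrics = metrics,
         paths = c(trials = trials_path,
                   fits = paste(fit_paths, collapse = ";"),
                   predictions = pred_path, metrics = metrics_path))
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    stop("pipeline failed at stage '", stage, "': ",
         attr(result, "condition")$message, call. = FALSE)
  }
  invisible(result)
}

#' Run a reduced validation grid end to end
#'
#' Builds the synthetic validation grid, fits the requested model to each
#' dataset and writes the recovery report.
#'
#' @param out_path output TSV path (`NULL` to skip writing).
#' @param models ground-truth models (named list).
#' @param theta0_values,mu_values,sigma_values grid values.
#' @param n_blocks blocks per simulated dataset.
#' @param fit_model `"ct"` or `"markov"`.
#' @param config a [fit_config()].
#' @param hyper an [hdp_hyper()].
#' @return The recovery report data.frame.
#' @export
run_validation <- function(out_path = NULL,
                           models = make_ground_truth_models(),
                           theta0_values = c(0.12, 0.18, 0.24),
                           mu_values = c(6, 8, 10),
                           sigma_values = c(1, 2, 3),
                           n_blocks = 20L, fit_model = c("ct", "markov"),
                           config = fit_config(), hyper = hdp_hyper()) {
  fit_model <- match.arg(fit_model)
  seqn <- generate_session(asrt_pattern(c(2, 4, 3, 1)), n_blocks = n_blocks,
                           seed = config$seed)
  grid <- validation_grid(models, theta0_values, mu_values, sigma_values,
                          seq = seqn, seed = config$seed)
  fits <- lapply(grid, function(ds) {
    if (fit_model == "ct") fit_ct(seqn, ds$trials, hyper, config)
    else fit_markov(seqn, ds$trials, hyper, config)
  })
  report <- recovery_report(grid, fits, seqn, config)
  if (!is.null(out_path)) {
    write_tsv(report, out_path, seed = config$seed, config = config)
  }
  report
}
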