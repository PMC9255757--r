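#' File formats
#'
#' Trial tables travel as tab-separated text with a fixed header
#' (`participant_id, session, block, trial, stimulus, trial_type,
#' pattern_phase, response, correct, rt_ms`); behavioural columns may be
#' empty for design-only files. Response times are stored in milliseconds
#' and converted to seconds internally. Posterior fits are serialized as
#' JSON-lines with a header record. Every file written by the package
#' starts with `#`-prefixed provenance comments (package version, seed,
#' configuration hash).
#'
#' @name cli_io
NULL

TRIAL_COLUMNS <- c("participant_id", "session", "block", "trial", "stimulus",
                   "trial_type", "pattern_phase", "response", "correct",
                   "rt_ms")

provenance_header <- function(seed = NA, config = NULL) {
  h <- c(sprintf("# cogtomo %s", as.character(utils::packageVersion("cogtomo"))),
         sprintf("# created %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
         sprintf("# seed %s", as.character(seed)))
  if (!is.null(config)) {
    flat <- paste(names(unlist(config)), unlist(config), sep = "=",
                  collapse = " ")
    h <- c(h, sprintf("# config %s", flat))
  }
  h
}

#' Write a trial table
#'
#' @param trials data.frame; missing schema columns are added empty.
#' @param path output file.
#' @param seed seed recorded in the provenance header.
#' @param config optional configuration recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, seed = NA, config = NULL) {
  for (col in TRIAL_COLUMNS) if (!col %in% names(trials)) trials[[col]] <- NA
  trials <- trials[, TRIAL_COLUMNS]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.table(trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial table
#'
#' Accepts the documented tab-separated schema; `#` comment lines are
#' skipped. Validates the stimulus alphabet, block monotonicity and
#' response-time positivity, reporting the first offending rows with line
#' numbers. Design-only files (empty behavioural columns) are valid.
#'
#' @param path input file.
#' @return data.frame with typed columns.
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("session", "block", "trial", "stimulus", "pattern_phase",
                "response", "correct")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$rt_ms <- as.numeric(df$rt_ms)
  bad_row_msg <- function(rows, what) {
    stop("schema violation in ", path, " (", what, ") at data rows: ",
         paste(utils::head(rows, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(df$stimulus %in% 1:4))
  if (length(bad) > 0) bad_row_msg(bad, "stimulus outside 1..4")
  bad <- which(!is.na(df$response) & !(df$response %in% 1:4))
  if (length(bad) > 0) bad_row_msg(bad, "response outside 1..4")
  bad <- which(!(df$trial_type %in% c("warmup", "pattern", "random")))
  if (length(bad) > 0) bad_row_msg(bad, "unknown trial_type")
  bad <- which(!is.na(df$rt_ms) & df$rt_ms <= 0)
  if (length(bad) > 0) bad_row_msg(bad, "non-positive rt_ms")
  d <- diff(df$block)
  bad <- which(d < 0) + 1L
  if (length(bad) > 0) bad_row_msg(bad, "block ids decrease")
  df
}

#' Reconstruct an `asrt_sequence` from a trial table
#'
#' @param trials trial table (as from [read_trials()]).
#' @param pattern the session's [asrt_pattern]; inferred from the pattern
#'   trials when omitted.
#' @return An `asrt_sequence`.
#' @export
sequence_from_trials <- function(trials, pattern = NULL) {
  if (is.null(pattern)) {
    pat_tr <- trials[trials$trial_type == "pattern" &
                       !is.na(trials$pattern_phase), ]
    if (nrow(pat_tr) == 0) stop("cannot infer pattern: no pattern trials",
                                call. = FALSE)
    elems <- vapply(1:4, function(ph) {
      s <- unique(pat_tr$stimulus[pat_tr$pattern_phase == ph])
      if (length(s) != 1) stop("inconsistent pattern phases", call. = FALSE)
      s
    }, 0L)
    pattern <- asrt_pattern(elems)
  }
  if (!"trial_global" %in% names(trials)) {
    trials$trial_global <- seq_len(nrow(trials))
  }
  structure(list(trials = trials, pattern = pattern,
                 n_blocks = length(unique(trials$block)),
                 block_length = max(trials$trial)),
            class = "asrt_sequence")
}

#' Serialize a fit to JSON-lines
#'
#' First line is a header record with the model type, configuration and
#' hyperparameters; each following line is one posterior sample.
#'
#' @param fit a `ct_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(record = "header", model = fit$model,
                 package_version = as.character(utils::packageVersion("cogtomo")),
                 config = unclass(fit$config), hyper = unclass(fit$hyper))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)), con)
  for (s in fit$samples) {
    rec <- list(record = "sample", chain = s$chain, step = s$step,
                slice_eps = s$slice_eps, lp = s$lp, occupied = s$occupied,
                n_states = s$hmm$n_states, transition = s$hmm$transition,
                emission = s$hmm$emission,
                later = list(theta0 = s$later$theta0, mu = s$later$mu,
                             sigma = s$later$sigma))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17)), con)
  }
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  cfg <- header$config
  config <- fit_config(preset = cfg$preset, n_chains = cfg$n_chains,
                       n_outer_steps = cfg$n_outer_steps,
                       n_inner_steps = cfg$n_inner_steps,
                       n_prediction_samples_per_chain =
                         cfg$n_prediction_samples_per_chain,
                       train_blocks = cfg$train_blocks,
                       test_blocks = cfg$test_blocks,
                       rt_floor_ms = cfg$rt_floor_ms, seed = cfg$seed,
                       max_tree_depth = cfg$max_tree_depth)
  hy <- header$hyper
  hyper <- hdp_hyper(alpha = hy$alpha, gamma = hy$gamma,
                     emission_base = hy$emission_base, k_max = hy$k_max,
                     alpha0 = hy$alpha0,
                     rt_priors = lapply(hy$rt_priors, as.numeric))
  samples <- lapply(lines[-1], function(ln) {
    r <- jsonlite::fromJSON(ln)
    posterior_sample(hmm_params(r$transition, r$emission),
                     later_params(r$later$theta0, r$later$mu, r$later$sigma),
                     slice_eps = if (is.null(r$slice_eps)) NA_real_ else r$slice_eps,
                     chain = r$chain, step = r$step,
                     lp = if (is.null(r$lp)) NA_real_ else r$lp,
                     occupied = if (is.null(r$occupied)) NA_integer_ else r$occupied)
  })
  new_ct_fit(samples, header$model, config, hyper)
}

#' Write a generic provenance-stamped TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @param seed,config recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
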