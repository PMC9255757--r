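#' Model-comparison metrics
#'
#' Explained variance of held-out response times, Kullback-Leibler
#' divergence between predictive distributions, error-trial rank and ROC
#' analyses of subjective probabilities, the higher-order learning score
#' that separates latent-state knowledge from triplet statistics, and the
#' normalized/decomposed performance summaries.
#'
#' @name evaluation
NULL

KL_EPS <- 1e-9

#' Explained-variance score
#'
#' Two conventions are supported and both are reported in batch outputs:
#' `corr2`, the squared Pearson correlation (free slope and intercept,
#' required e.g. when predictions are a binary high/low variable), and
#' `ssr`, `1 - SSE/SST` (no free parameters; can be negative). `corr2` is
#' the default.
#'
#' @param predicted,observed equal-length numeric vectors (>= 3 values).
#' @param variant `"corr2"` or `"ssr"`.
#' @return Scalar score.
#' @export
r2_score <- function(predicted, observed, variant = c("corr2", "ssr")) {
  variant <- match.arg(variant)
  if (length(predicted) != length(observed) || length(observed) < 3) {
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(predicted) < 1e-14 || stats::sd(observed) < 1e-14) {
    stop("zero variance in predicted or observed values", call. = FALSE)
  }
  if (variant == "corr2") {
    stats::cor(predicted, observed)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' Mean Kullback-Leibler divergence over trials
#'
#' Per trial, `KL(true || model) = sum_i p_i (log p_i - log phat_i)` with
#' the model probabilities floored at `eps` and renormalized; averaged over
#' trials. The ground-truth convention for ASRT is probability 1.0 on the
#' pattern element for pattern trials and 0.25 everywhere for random
#' trials.
#'
#' @param true_probs,model_probs `T x 4` matrices of per-trial
#'   distributions.
#' @param eps floor applied to model probabilities.
#' @return Scalar mean divergence (non-negative).
#' @export
kl_mean <- function(true_probs, model_probs, eps = KL_EPS) {
  true_probs <- as.matrix(true_probs)
  model_probs <- as.matrix(model_probs)
  if (!all(dim(true_probs) == dim(model_probs))) {
    stop("dimension mismatch", call. = FALSE)
  }
  if (any(abs(rowSums(true_probs) - 1) > 1e-6) ||
      any(abs(rowSums(model_probs) - 1) > 1e-6)) {
    stop("rows must be normalized distributions", call. = FALSE)
  }
  m <- pmax(model_probs, eps)
  m <- m / rowSums(m)
  terms <- true_probs * (log(pmax(true_probs, 1e-300)) - log(m))
  terms[true_probs == 0] <- 0
  mean(rowSums(terms))
}

#' Ground-truth ASRT trial probabilities
#'
#' Probability 1 on the pattern element for pattern trials, uniform 0.25
#' for warm-up and random trials.
#'
#' @param seq an `asrt_sequence`.
#' @return A `T x 4` matrix.
#' @export
ground_truth_probs <- function(seq) {
  tr <- seq$trials
  out <- matrix(0.25, nrow(tr), 4)
  pat <- which(tr$trial_type == "pattern")
  out[pat, ] <- 0
  out[cbind(pat, tr$stimulus[pat])] <- 1
  out
}

# fractional top-rank: 1/k when tied with k-1 others at the maximum
ranked_first_fraction <- function(pred_rows, targets) {
  if (length(targets) == 0) return(NA_real_)
  mean(vapply(seq_along(targets), function(i) {
    row <- pred_rows[i, ]
    mx <- max(row)
    if (row[targets[i]] < mx - 1e-12) 0 else 1 / sum(row >= mx - 1e-12)
  }, 0))
}

#' Rank analysis of errors
#'
#' Among the four subjective probabilities of each trial, asks how often
#' (a) the actual stimulus and (b) the pressed key carry the top
#' probability, separately for correct and incorrect trials. Ties at the
#' top are split fractionally (a k-way tie contributes 1/k), so chance
#' level is exactly 0.25.
#'
#' @param predictions `T x 4` matrix of subjective probabilities.
#' @param trials trial table with `stimulus`, `response`, `correct`.
#' @return data.frame with columns `target` (stimulus/response), `trials`
#'   (correct/incorrect), `n`, `fraction_ranked_first`.
#' @export
error_rank_analysis <- function(predictions, trials) {
  if (nrow(predictions) != nrow(trials)) stop("misaligned inputs", call. = FALSE)
  if (any(is.na(trials$response))) {
    stop("missing responses", call. = FALSE)
  }
  cells <- expand.grid(target = c("stimulus", "response"),
                       trials = c("correct", "incorrect"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- if (cells$trials[i] == "correct") trials$correct == 1
           else trials$correct == 0
    tgt <- if (cells$target[i] == "stimulus") trials$stimulus[sel]
           else trials$response[sel]
    data.frame(target = cells$target[i], trials = cells$trials[i],
               n = sum(sel),
               fraction_ranked_first =
                 ranked_first_fraction(predictions[sel, , drop = FALSE], tgt))
  })
  do.call(rbind, rows)
}

#' ROC analysis of error prediction
#'
#' Uses the subjective probability of the actual stimulus as a score for
#' the trial being answered correctly, sweeps a threshold over the score
#' values and traces the ROC; the area under the curve is computed by the
#' trapezoid rule (equivalently, the Mann-Whitney statistic with ties
#' counted 1/2).
#'
#' @param predictions `T x 4` matrix of subjective probabilities.
#' @param trials trial table with `stimulus` and `correct` (both classes
#'   present).
#' @return List with `points` (data.frame `fpr`, `tpr`, one row per
#'   distinct score plus the two endpoints) and `auc`.
#' @export
error_roc <- function(predictions, trials) {
  if (nrow(predictions) != nrow(trials)) stop("misaligned inputs", call. = FALSE)
  score <- predictions[cbind(seq_len(nrow(trials)), trials$stimulus)]
  label <- trials$correct == 1
  if (all(label) || !any(label)) {
    stop("both correct and incorrect trials are required", call. = FALSE)
  }
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- data.frame(fpr = 0, tpr = 0)
  for (th in thr) {
    pred_pos <- score >= th
    pts <- rbind(pts, data.frame(fpr = sum(pred_pos & !label) / sum(!label),
                                 tpr = sum(pred_pos & label) / sum(label)))
  }
  pts <- unique(pts)
  if (utils::tail(pts$fpr, 1) != 1 || utils::tail(pts$tpr, 1) != 1) {
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Higher-order learning score
#'
#' Considers trials ending a high triplet and compares matched conditions
#' that share the same observed three-stimulus window but differ in latent
#' role: windows whose third (and first) element is a pattern trial versus
#' windows whose third element is a random trial. The trigram model cannot
#' distinguish them; an observer tracking the latent state can. The score
#' is the mean response time (or predicted response time) of the
#' random-third condition minus the pattern-third condition, averaged over
#' observed triplet identities present in both conditions; positive values
#' mean faster responses on pattern trials. Windows straddling block
#' boundaries and trials failing [valid_trial_mask()] are excluded.
#'
#' @param trials trial table with `trial_type`, `stimulus`, `block`,
#'   `correct`, `rt_ms`.
#' @param rts values to score, in any unit: measured response times or
#'   model predictions, aligned with `trials`; defaults to
#'   `trials$rt_ms`.
#' @param labels triplet labels as from [label_triplets()]; recomputed from
#'   `pattern` when omitted.
#' @param pattern an [asrt_pattern] used to recompute labels.
#' @param config a [fit_config()] for the validity mask.
#' @return Scalar score in the unit of `rts`.
#' @export
higher_order_score <- function(trials, rts = trials$rt_ms, labels = NULL,
                               pattern = NULL, config = fit_config()) {
  if (is.null(labels)) {
    if (is.null(pattern)) stop("supply labels or pattern", call. = FALSE)
    fake <- structure(list(trials = trials), class = "asrt_sequence")
    labels <- label_triplets(fake, pattern)
  }
  n <- nrow(trials)
  mask <- valid_trial_mask(trials, config)
  third <- which(labels == "high" & mask)
  third <- third[third > 2]
  same_block <- trials$block[third] == trials$block[third - 2L]
  third <- third[same_block]
  if (length(third) == 0) stop("no usable high-triplet windows", call. = FALSE)
  key <- paste(trials$stimulus[third - 2L], trials$stimulus[third - 1L],
               trials$stimulus[third], sep = "-")
  type3 <- trials$trial_type[third]
  keep <- type3 %in% c("pattern", "random")
  key <- key[keep]; type3 <- type3[keep]; vals <- rts[third][keep]
  both <- intersect(unique(key[type3 == "pattern"]),
                    unique(key[type3 == "random"]))
  if (length(both) == 0) {
    missing_cond <- if (!any(type3 == "pattern")) "pattern-third"
                    else "random-third"
    stop("no matched triplets: the ", missing_cond,
         " condition is empty or never overlaps", call. = FALSE)
  }
  diffs <- vapply(both, function(k) {
    mean(vals[key == k & type3 == "random"]) -
      mean(vals[key == k & type3 == "pattern"])
  }, 0)
  mean(diffs)
}

#' Normalized model performance
#'
#' The margin by which the full internal-model fit outperforms the Markov
#' model: `ct_r2 - markov_r2` (vectorized; alignment preserved).
#'
#' @param ct_r2,markov_r2 finite numeric vectors.
#' @return `ct_r2 - markov_r2`.
#' @export
normalized_ct <- function(ct_r2, markov_r2) {
  stopifnot(is.finite(ct_r2), is.finite(markov_r2))
  ct_r2 - markov_r2
}

#' Linear decomposition of model predictions
#'
#' Ordinary least squares of the full-model trial-by-trial predictions on
#' the Markov and ideal-observer predictions plus an offset, quantifying
#' how much of the inferred internal model is a blend of the two reference
#' structures.
#'
#' @param ct_pred,markov_pred,ideal_pred aligned numeric vectors (length >=
#'   4).
#' @return List with `weights` (named: markov, ideal), `offset`, `r2` of
#'   the fit.
#' @export
decompose_ct <- function(ct_pred, markov_pred, ideal_pred) {
  n <- length(ct_pred)
  if (length(markov_pred) != n || length(ideal_pred) != n || n < 4) {
    stop("need aligned vectors of length >= 4", call. = FALSE)
  }
  X <- cbind(1, markov_pred, ideal_pred)
  kap <- kappa(X, exact = TRUE)
  if (kap > 1e8) {
    stop("collinear predictors (condition number ", format(kap, digits = 3),
         ")", call. = FALSE)
  }
  fit <- stats::lm.fit(X, ct_pred)
  fitted <- X %*% fit$coefficients
  sst <- sum((ct_pred - mean(ct_pred))^2)
  r2 <- if (sst > 0) 1 - sum((ct_pred - fitted)^2) / sst else 1
  list(weights = c(markov = unname(fit$coefficients[2]),
                   ideal = unname(fit$coefficients[3])),
       offset = unname(fit$coefficients[1]), r2 = r2)
}

#' Batch evaluation of model predictions
#'
#' Computes both explained-variance variants of predicted versus observed
#' response times on the valid trials of a test set.
#'
#' @param predicted_rt_s predicted response times in seconds, aligned with
#'   `trials`.
#' @param trials trial table for the test blocks.
#' @param config a [fit_config()].
#' @return data.frame with columns `metric`, `variant`, `value`, `n`.
#' @export
evaluate_rt_predictions <- function(predicted_rt_s, trials,
                                    config = fit_config()) {
  mask <- valid_trial_mask(trials, config)
  obs <- trials$rt_ms[mask] / 1000
  pred <- predicted_rt_s[mask]
  data.frame(metric = "rt_r2", variant = c("corr2", "ssr"),
             value = c(r2_score(pred, obs, "corr2"),
                       r2_score(pred, obs, "ssr")),
             n = sum(mask))
}
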