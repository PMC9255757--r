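#' Discrete hidden Markov internal models
#'
#' The participant's internal model of the stimulus stream is a discrete HMM:
#' latent states with transition matrix `pi` (K x K) and emission matrix
#' `phi` (K x 4) over the four stimulus identities. Beliefs over the latent
#' state are updated by exact Bayesian filtering, and next-stimulus
#' predictions are obtained by propagating the belief one step and
#' marginalizing through the emissions.
#'
#' @name models
NULL

PROB_TOL <- 1e-10

#' Construct HMM parameters
#'
#' @param transition K x K row-stochastic matrix, `transition[i, j] =
#'   P(S_{t+1} = j | S_t = i)`.
#' @param emission K x 4 row-stochastic matrix, `emission[i, k] =
#'   P(Y_t = k | S_t = i)`.
#' @return Object of class `hmm_params` with fields `n_states`, `transition`,
#'   `emission`.
#' @export
hmm_params <- function(transition, emission) {
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  K <- nrow(transition)
  if (ncol(transition) != K) stop("transition must be square", call. = FALSE)
  if (nrow(emission) != K || ncol(emission) != 4L) {
    stop("emission must be K x 4", call. = FALSE)
  }
  check_stochastic(transition, "transition")
  check_stochastic(emission, "emission")
  structure(list(n_states = K, transition = unname(transition),
                 emission = unname(emission)),
            class = "hmm_params")
}

check_stochastic <- function(m, what) {
  if (any(m < -PROB_TOL)) stop(what, " has negative entries", call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-8)) {
    stop(what, " rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("HMM internal model: %d states, 4 observations\n", x$n_states))
  invisible(x)
}

#' Construct a belief over latent states
#'
#' @param weights non-negative K-vector summing to 1.
#' @return Numeric vector of class `belief`.
#' @export
belief <- function(weights) {
  weights <- as.numeric(weights)
  if (any(weights < -PROB_TOL) || abs(sum(weights) - 1) > 1e-8) {
    stop("belief must be a probability vector", call. = FALSE)
  }
  structure(weights, class = "belief")
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector for eigenvalue 1, when unique; falls back to the uniform
#' distribution when the unit eigenspace is degenerate or complex. Used as
#' the default initial belief: the least informative belief that is
#' dynamically consistent with the model.
#'
#' @param transition K x K row-stochastic matrix.
#' @return A [belief()].
#' @export
stationary_belief <- function(transition) {
  K <- nrow(transition)
  ev <- eigen(t(transition))
  unit <- which(abs(ev$values - 1) < 1e-8)
  if (length(unit) != 1L) return(belief(rep(1 / K, K)))
  v <- ev$vectors[, unit]
  if (max(abs(Im(v))) > 1e-8) return(belief(rep(1 / K, K)))
  v <- Re(v)
  if (all(v <= 1e-12)) v <- -v
  if (any(v < -1e-8)) return(belief(rep(1 / K, K)))
  v[v < 0] <- 0
  belief(v / sum(v))
}

#' One filtering step
#'
#' Propagates the belief over `S_{t-1}` through the transition matrix,
#' multiplies by the emission likelihood of the observed stimulus, and
#' renormalizes: the posterior `p(s_t | y_1..y_t)`.
#'
#' @param bel current [belief()] over `S_{t-1}`.
#' @param observation observed stimulus in `1:4`.
#' @param hmm an [hmm_params()].
#' @return Updated [belief()] over `S_t`.
#' @export
update_belief <- function(bel, observation, hmm) {
  stopifnot(observation %in% 1:4)
  prior <- as.numeric(crossprod(hmm$transition, as.numeric(bel)))
  un <- prior * hmm$emission[, observation]
  z <- sum(un)
  if (z <= 0) {
    stop("observation ", observation,
         " has zero probability under every reachable state", call. = FALSE)
  }
  belief(un / z)
}

#' Predict the next stimulus
#'
#' One-step propagation of the belief through the transitions followed by
#' marginalization through the emissions:
#' `p(y_{t+1} | y_1..y_t) = sum_{s_t, s_{t+1}} phi[s_{t+1}, y] pi[s_t, s_{t+1}] belief[s_t]`.
#'
#' @inheritParams update_belief
#' @return Numeric 4-vector of next-stimulus probabilities.
#' @export
predict_next <- function(bel, hmm) {
  prior_next <- as.numeric(crossprod(hmm$transition, as.numeric(bel)))
  p <- as.numeric(crossprod(hmm$emission, prior_next))
  p / sum(p)
}

#' Predictions for every trial of a sequence
#'
#' For each trial `t` returns the model's predictive distribution over the
#' upcoming stimulus *before* observing it, filtering through all stimuli
#' (warm-up and error trials included) and carrying the belief across block
#' boundaries.
#'
#' @param hmm an [hmm_params()].
#' @param seq an `asrt_sequence` or an integer vector of stimuli.
#' @param initial_belief starting belief; default is [stationary_belief()] of
#'   the transition matrix.
#' @return A `T x 4` matrix of predictive probabilities; row `t` is the
#'   prediction made before trial `t`.
#' @export
sequence_predictions <- function(hmm, seq, initial_belief = NULL) {
  y <- stimuli_of(seq)
  if (length(y) == 0L) stop("empty sequence", call. = FALSE)
  if (is.null(initial_belief)) initial_belief <- stationary_belief(hmm$transition)
  res <- filter_hmm_cpp(hmm$transition, hmm$emission, y,
                        as.numeric(initial_belief), 0)
  res$predictions
}

stimuli_of <- function(seq) {
  if (inherits(seq, "asrt_sequence")) {
    as.integer(seq$trials$stimulus)
  } else {
    as.integer(seq)
  }
}

#' Truncate a belief to its 1 - eps support
#'
#' Keeps the smallest set of highest-mass states whose total mass is at least
#' `1 - eps`, zeroes the rest and renormalizes; `eps = 0` keeps all states.
#' This is the slice-truncation used to keep filtering finite under the
#' nonparametric prior.
#'
#' @param bel a [belief()].
#' @param eps slicing variable in `[0, 1)`.
#' @return A [belief()] supported on the retained states.
#' @export
truncate_belief <- function(bel, eps) {
  w <- as.numeric(bel)
  if (eps <= 0) return(belief(w))
  ord <- order(w, decreasing = TRUE)
  keep_n <- which(cumsum(w[ord]) >= 1 - eps)[1]
  keep <- ord[seq_len(keep_n)]
  out <- numeric(length(w))
  out[keep] <- w[keep]
  belief(out / sum(out))
}

#' The ideal observer of the ASRT task
#'
#' The true generative process of the ASRT stream is an 8-state HMM with
#' states Pattern1, Random1, Pattern2, Random2, Pattern3, Random3, Pattern4,
#' Random4: Pattern_i emits the i-th pattern element with probability 1 and
#' moves to Random_i; Random_i emits uniformly and moves to Pattern_{i+1}
#' (cyclically).
#'
#' @param pattern an [asrt_pattern].
#' @return An [hmm_params()] with 8 states; states are ordered Pattern1,
#'   Random1, ..., Pattern4, Random4.
#' @export
ideal_observer <- function(pattern) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  K <- 8L
  tr <- matrix(0, K, K)
  em <- matrix(0, K, 4L)
  for (i in 1:4) {
    p_i <- 2L * i - 1L  # Pattern_i
    r_i <- 2L * i       # Random_i
    tr[p_i, r_i] <- 1
    tr[r_i, 2L * (i %% 4L) + 1L] <- 1  # Random_i -> Pattern_{i+1}
    em[p_i, pattern$elements[i]] <- 1
    em[r_i, ] <- 0.25
  }
  hmm_params(tr, em)
}

#' Embed a first-order Markov model as an HMM
#'
#' An observation-level Markov model is the HMM whose states are the four
#' stimuli themselves: identity emissions and the given transition matrix.
#'
#' @param transition4 4 x 4 row-stochastic matrix of next-stimulus
#'   conditionals.
#' @return An [hmm_params()] with `K = 4` and identity emissions.
#' @export
markov_as_hmm <- function(transition4) {
  transition4 <- as.matrix(transition4)
  if (!all(dim(transition4) == c(4L, 4L))) {
    stop("transition4 must be 4 x 4", call. = FALSE)
  }
  check_stochastic(transition4, "transition4")
  hmm_params(transition4, diag(4))
}

#' Maximum-likelihood Markov model of a stimulus sequence
#'
#' Row-wise empirical next-stimulus frequencies with add-`smooth`
#' regularization (so rows stay stochastic at small samples).
#'
#' @param seq an `asrt_sequence` or stimulus vector.
#' @param smooth pseudo-count per cell (default 0.5).
#' @return A 4 x 4 transition matrix.
#' @export
fit_markov_ml <- function(seq, smooth = 0.5) {
  y <- stimuli_of(seq)
  counts <- matrix(smooth, 4, 4)
  for (t in seq_along(y)[-1]) {
    counts[y[t - 1L], y[t]] <- counts[y[t - 1L], y[t]] + 1
  }
  counts / rowSums(counts)
}

#' Trigram (triplet) model predictions
#'
#' The field-standard ASRT learning measure classifies trials by whether the
#' stimulus continues a high-probability triplet: the pattern successor of
#' the stimulus two trials back. The trigram predictor assigns 0.625 to that
#' continuation and 0.125 to each alternative, and a uniform 0.25 on the
#' first two trials of each block where no two-back context exists. The
#' exact values are conventional (trials are only ever *classified* as high
#' or low); they equal the analytic continuation probabilities of the ASRT
#' generative process, see [trigram_continuation_probs()].
#'
#' @param seq an `asrt_sequence`.
#' @param pattern pattern to use; defaults to the sequence's own.
#' @return A list with `predictions` (T x 4 matrix) and `labels`
#'   (high/low/undefined per trial, as [label_triplets()]).
#' @export
trigram_predictions <- function(seq, pattern = seq$pattern) {
  tr <- seq$trials
  n <- nrow(tr)
  pred <- matrix(0.25, n, 4)
  two_back <- c(NA_integer_, NA_integer_, tr$stimulus[seq_len(n - 2L)])
  defined <- tr$trial > 2L
  succ <- pattern_successor(ifelse(is.na(two_back), 1L, two_back), pattern)
  for (t in which(defined)) {
    pred[t, ] <- 0.125
    pred[t, succ[t]] <- 0.625
  }
  list(predictions = pred, labels = label_triplets(seq, pattern))
}

#' Analytic trigram continuation probabilities
#'
#' Derives the high- and low-triplet continuation probabilities of the ASRT
#' generative process by exact marginalization over trial parity, using the
#' ideal-observer HMM: under the stationary state distribution, compute the
#' joint distribution of the stimulus two back and the upcoming stimulus, and
#' read off the probability that the upcoming stimulus is the pattern
#' successor of the two-back stimulus. A pattern trial follows its two-back
#' pattern trial deterministically; a random trial matches any continuation
#' with probability 1/4; the two parities are equally frequent, giving
#' (1 + 1/4) / 2 = 0.625 for the successor and 0.125 per alternative.
#'
#' @param pattern an [asrt_pattern]; the result is pattern-invariant.
#' @return Named numeric vector with elements `high` (successor continuation)
#'   and `low` (each non-successor continuation).
#' @export
trigram_continuation_probs <- function(pattern = asrt_pattern(1:4)) {
  io <- ideal_observer(pattern)
  st <- as.numeric(stationary_belief(io$transition))
  tr <- io$transition
  em <- io$emission
  tr2 <- tr %*% tr
  p_high <- 0
  # joint over (Y_{t-1} = a, Y_{t+1} = b) given S_{t-1} ~ stationary
  for (s in seq_len(io$n_states)) {
    for (a in 1:4) {
      p_sa <- st[s] * em[s, a]
      if (p_sa == 0) next
      succ_a <- pattern_successor(a, pattern)
      # distribution of Y_{t+1}: two transitions ahead of S_{t-1}
      p_next <- as.numeric(tr2[s, ] %*% em)
      p_high <- p_high + p_sa * p_next[succ_a]
    }
  }
  low <- (1 - p_high) / 3
  c(high = p_high, low = low)
}

#' Serialize HMM parameters to JSON
#'
#' @param hmm an [hmm_params()].
#' @return A JSON string with fields `n_states`, `transition`, `emission`;
#'   exact round-trip through [hmm_from_json()].
#' @export
hmm_to_json <- function(hmm) {
  jsonlite::toJSON(list(n_states = hmm$n_states,
                        transition = hmm$transition,
                        emission = hmm$emission),
                   digits = I(17), auto_unbox = TRUE)
}

#' @rdname hmm_to_json
#' @param json JSON string produced by [hmm_to_json()].
#' @export
hmm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  hmm_params(x$transition, x$emission)
}
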