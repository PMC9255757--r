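# shared fixtures, all generated in code

default_pattern <- function() asrt_pattern(c(2, 4, 3, 1))

# a small random (strictly positive) HMM, reproducible
random_hmm <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- matrix(stats::rgamma(K * K, 1), K)
  em <- matrix(stats::rgamma(K * 4, 1), K, 4)
  hmm_params(tr / rowSums(tr), em / rowSums(em))
}

# brute-force filtered posterior over the final state by enumerating all
# latent paths; initial belief is over S_0 (one transition before trial 1)
enumerate_posterior <- function(hmm, y, init) {
  K <- hmm$n_states
  T_len <- length(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  w <- apply(paths, 1, function(pth) {
    p <- sum(init * hmm$transition[, pth[1]]) * hmm$emission[pth[1], y[1]]
    if (T_len > 1) {
      for (t in 2:T_len) {
        p <- p * hmm$transition[pth[t - 1], pth[t]] * hmm$emission[pth[t], y[t]]
      }
    }
    p
  })
  post <- vapply(seq_len(K), function(k) sum(w[paths[, T_len] == k]), 0)
  post / sum(post)
}

# one simulated Markov-internal-model participant
markov_participant <- function(seed = 7) {
  set.seed(seed)
  tr4 <- matrix(stats::rgamma(16, 0.6), 4)
  tr4 <- tr4 / rowSums(tr4)
  synthetic_participant(markov_as_hmm(tr4), later_params(0.18, 8, 2))
}

desk_test_config <- function(...) fit_config("desk", ...)
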