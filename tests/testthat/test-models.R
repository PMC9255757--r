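test_that("belief filtering matches exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    K <- sample(2:4, 1)
    T_len <- sample(3:7, 1)
    hmm <- random_hmm(K)
    y <- sample(1:4, T_len, replace = TRUE)
    init <- stats::rgamma(K, 1)
    init <- init / sum(init)
    oracle <- enumerate_posterior(hmm, y, init)
    b <- belief(init)
    for (t in seq_len(T_len)) b <- update_belief(b, y[t], hmm)
    expect_lt(max(abs(as.numeric(b) - oracle)), 1e-10)
  }
})

test_that("identity emissions collapse the belief onto the observation", {
  hmm <- hmm_params(matrix(0.25, 4, 4), diag(4))
  for (obs in 1:4) {
    b <- update_belief(belief(c(0.1, 0.2, 0.3, 0.4)), obs, hmm)
    expect_equal(as.numeric(b), as.numeric(obs == 1:4))
  }
})

test_that("impossible observations raise an explicit error", {
  hmm <- hmm_params(diag(4), diag(4))  # state i always emits i, stays put
  b <- belief(c(1, 0, 0, 0))
  expect_error(update_belief(b, 2, hmm), "zero probability")
})

test_that("predictions are normalized and uniform under full symmetry", {
  hmm <- hmm_params(matrix(0.25, 4, 4), matrix(0.25, 4, 4))
  p <- predict_next(belief(rep(0.25, 4)), hmm)
  expect_equal(p, rep(0.25, 4))
  set.seed(5)
  for (rep in 1:10) {
    hmm <- random_hmm(sample(2:6, 1))
    b <- stats::rgamma(hmm$n_states, 1)
    expect_equal(sum(predict_next(belief(b / sum(b)), hmm)), 1,
                 tolerance = 1e-12)
  }
})

test_that("the ideal observer has the exact 8-state structure", {
  pat <- default_pattern()
  io <- ideal_observer(pat)
  expect_equal(io$n_states, 8)
  # random rows uniform, pattern rows one-hot on the pattern element
  for (i in 1:4) {
    expect_equal(io$emission[2 * i, ], rep(0.25, 4))
    expect_equal(io$emission[2 * i - 1, ],
                 as.numeric(pat$elements[i] == 1:4))
  }
  # deterministic cycle Pattern_i -> Random_i -> Pattern_{i+1}
  expect_true(all(io$transition %in% c(0, 1)))
  expect_equal(rowSums(io$transition), rep(1, 8))

  # one-step observable conditionals are uniform regardless of the previous
  # stimulus (matrix algebra: condition the stationary state on Y_{t-1})
  st <- as.numeric(stationary_belief(io$transition))
  for (a in 1:4) {
    joint <- st * io$emission[, a]
    cond_state <- joint / sum(joint)
    p_next <- as.numeric(crossprod(io$emission,
                                   crossprod(io$transition, cond_state)))
    expect_equal(p_next, rep(0.25, 4), tolerance = 1e-12)
  }
})

test_that("filtering the ideal observer resolves the pattern phase", {
  pat <- default_pattern()
  io <- ideal_observer(pat)
  # warm-up trials can contradict the deterministic alternation (that is the
  # documented zero-probability error), so filter the alternating part only
  s <- generate_session(pat, n_blocks = 1, block_warmup = 0, seed = 21)
  preds <- sequence_predictions(io, s)
  beliefs <- cogtomo:::filter_hmm_cpp(io$transition, io$emission,
                                      as.integer(s$trials$stimulus),
                                      as.numeric(stationary_belief(io$transition)),
                                      0)$beliefs
  # after the first full pattern cycle the phase is known
  after <- s$trials$trial > 8
  phase_mass <- apply(beliefs[after, , drop = FALSE], 1, max)
  expect_true(all(phase_mass >= 0.999))
  # pattern trials predicted with probability ~1, random trials uniform
  pt <- which(s$trials$trial_type == "pattern" & after)
  expect_true(all(preds[cbind(pt, s$trials$stimulus[pt])] > 1 - 1e-6))
  rnd <- which(s$trials$trial_type == "random" & after)
  expect_true(max(abs(preds[rnd, ] - 0.25)) < 1e-6)
})

test_that("sequence predictions compose update/predict and carry across blocks", {
  set.seed(33)
  hmm <- random_hmm(3)
  s <- generate_session(default_pattern(), n_blocks = 2, seed = 34)
  y <- s$trials$stimulus[1:50]
  init <- stationary_belief(hmm$transition)
  preds <- sequence_predictions(hmm, y, init)
  expect_equal(nrow(preds), 50)
  b <- init
  for (t in 1:50) {
    expect_equal(preds[t, ], predict_next(b, hmm), tolerance = 1e-12)
    b <- update_belief(b, y[t], hmm)
  }
  # single-state model: every prediction equals the emission row
  one <- hmm_params(matrix(1, 1, 1), matrix(c(0.1, 0.2, 0.3, 0.4), 1))
  p1 <- sequence_predictions(one, y)
  expect_true(all(apply(p1, 1, function(r)
    isTRUE(all.equal(r, c(0.1, 0.2, 0.3, 0.4))))))
})

test_that("a Markov model embedded as an HMM reproduces direct conditionals", {
  set.seed(44)
  tr4 <- matrix(stats::rgamma(16, 1), 4)
  tr4 <- tr4 / rowSums(tr4)
  hmm <- markov_as_hmm(tr4)
  expect_equal(hmm$emission, diag(4))
  y <- sample(1:4, 60, replace = TRUE)
  preds <- sequence_predictions(hmm, y)
  for (t in 2:60) {
    expect_equal(preds[t, ], tr4[y[t - 1], ], tolerance = 1e-12)
  }
  # round-trip: one-step observable conditionals recover transition4
  recovered <- t(vapply(1:4, function(a) {
    as.numeric(predict_next(belief(as.numeric(a == 1:4)), hmm))
  }, numeric(4)))
  expect_equal(recovered, tr4, tolerance = 1e-12)
  expect_error(markov_as_hmm(matrix(1, 4, 4)), "sum to 1")
})

test_that("the ML Markov model of long ASRT data approaches uniform", {
  s <- generate_session(default_pattern(), n_blocks = 120, seed = 55)
  tr4 <- fit_markov_ml(s)
  expect_lt(max(abs(tr4 - 0.25)), 0.02)
})

test_that("trigram predictions carry the analytic high/low probabilities", {
  s <- generate_session(default_pattern(), n_blocks = 3, seed = 66)
  tg <- trigram_predictions(s)
  first_two <- s$trials$trial <= 2
  expect_true(all(tg$predictions[first_two, ] == 0.25))
  later <- tg$predictions[!first_two, , drop = FALSE]
  expect_true(all(apply(later, 1, max) == 0.625))
  expect_true(all(apply(later, 1, min) == 0.125))
  expect_equal(rowSums(tg$predictions), rep(1, nrow(tg$predictions)))
  # labels point at the 0.625 element
  hi <- which(tg$labels == "high")
  expect_true(all(tg$predictions[cbind(hi, s$trials$stimulus[hi])] == 0.625))
})

test_that("analytic trigram probabilities derive from parity marginalization", {
  for (pat in canonical_patterns()[1:3]) {
    pr <- trigram_continuation_probs(pat)
    expect_equal(unname(pr["high"]), 0.625, tolerance = 1e-12)
    expect_equal(unname(pr["low"]), 0.125, tolerance = 1e-12)
    expect_equal(unname(pr["high"] + 3 * pr["low"]), 1, tolerance = 1e-12)
  }
  # the parity argument: pattern parity contributes certainty, random parity
  # contributes chance, each with weight 1/2
  expect_equal(0.5 * 1 + 0.5 * 0.25, 0.625)
})

test_that("slice truncation keeps at least 1 - eps of the belief mass", {
  set.seed(77)
  for (rep in 1:20) {
    K <- sample(4:12, 1)
    w <- stats::rgamma(K, 0.5)
    b <- belief(w / sum(w))
    eps <- stats::runif(1, 0.02, 0.2)
    tb <- truncate_belief(b, eps)
    kept <- as.numeric(tb) > 0
    expect_gte(sum(as.numeric(b)[kept]), 1 - eps)
    expect_equal(sum(as.numeric(tb)), 1, tolerance = 1e-12)
    expect_equal(as.numeric(truncate_belief(b, 0)), as.numeric(b))
  }
})

test_that("HMM JSON serialization round-trips exactly", {
  hmm <- random_hmm(5, seed = 88)
  back <- hmm_from_json(hmm_to_json(hmm))
  expect_identical(back$transition, hmm$transition)
  expect_identical(back$emission, hmm$emission)
  expect_identical(back$n_states, hmm$n_states)
})

test_that("stationary beliefs are fixed points; degenerate cases fall back", {
  set.seed(99)
  tr <- matrix(stats::rgamma(25, 1), 5)
  tr <- tr / rowSums(tr)
  st <- as.numeric(stationary_belief(tr))
  expect_lt(max(abs(as.numeric(crossprod(tr, st)) - st)), 1e-10)
  # two disconnected components: unit eigenspace is degenerate -> uniform
  block <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0),
                 c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5))
  expect_equal(as.numeric(stationary_belief(block)), rep(0.25, 4))
})
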