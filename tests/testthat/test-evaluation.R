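test_that("explained-variance variants separate as designed", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(r2_score(x, x, "corr2"), 1)
  expect_equal(r2_score(x, x, "ssr"), 1)
  # anti-correlated: corr2 blind to the sign, ssr penalized
  y <- -x + 6
  expect_equal(r2_score(x, y, "corr2"), 1)
  expect_lte(r2_score(x, y, "ssr"), 0)
  # hand-computed 5-point example: pred (1,2,3,4,5), obs (2,2,4,4,6);
  # sample cov = 2.5, var_x = 2.5, var_y = 2.8 -> r2 = 2.5^2/(2.5*2.8);
  # SSE = 1+0+1+0+1 = 3, SST = 11.2
  obs <- c(2, 2, 4, 4, 6)
  expect_equal(r2_score(x, obs, "corr2"), 6.25 / 7)
  expect_equal(r2_score(x, obs, "ssr"), 1 - 3 / 11.2)
  # corr2 is affine-invariant in the predictions, ssr is not
  expect_equal(r2_score(10 * x + 3, obs, "corr2"),
               r2_score(x, obs, "corr2"))
  expect_false(isTRUE(all.equal(r2_score(10 * x + 3, obs, "ssr"),
                                r2_score(x, obs, "ssr"))))
  expect_error(r2_score(rep(1, 5), obs), "zero variance")
  expect_error(r2_score(1:2, 1:2), "at least 3")
})

test_that("mean KL divergence has the closed-form and zero properties", {
  u <- matrix(0.25, 3, 4)
  expect_equal(kl_mean(u, u), 0)
  onehot <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(kl_mean(onehot, matrix(0.25, 1, 4)), log(4))
  # mean over trials is the average of per-trial divergences
  two_true <- rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  two_model <- rbind(c(0.25, 0.25, 0.25, 0.25), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(kl_mean(two_true, two_model), log(4) / 2)
  # non-negative on random pairs
  set.seed(12)
  a <- matrix(stats::rgamma(40, 1), 10, 4); a <- a / rowSums(a)
  b <- matrix(stats::rgamma(40, 1), 10, 4); b <- b / rowSums(b)
  expect_gte(kl_mean(a, b), 0)
  expect_error(kl_mean(a, 2 * b), "normalized")
})

test_that("ground-truth probabilities encode the ASRT convention", {
  s <- generate_session(default_pattern(), n_blocks = 1, seed = 3)
  gt <- ground_truth_probs(s)
  pt <- s$trials$trial_type == "pattern"
  expect_true(all(gt[cbind(which(pt), s$trials$stimulus[pt])] == 1))
  expect_true(all(gt[!pt, ] == 0.25))
})

test_that("rank analysis splits ties fractionally and hits chance at uniform", {
  n <- 40
  set.seed(7)
  trials <- data.frame(stimulus = sample(1:4, n, TRUE),
                       response = sample(1:4, n, TRUE),
                       correct = rep(c(1, 0), n / 2))
  uni <- matrix(0.25, n, 4)
  res <- error_rank_analysis(uni, trials)
  expect_equal(res$fraction_ranked_first, rep(0.25, 4))
  # model always puts 0.625 on the pressed key
  follow <- matrix(0.125, n, 4)
  follow[cbind(1:n, trials$response)] <- 0.625
  res2 <- error_rank_analysis(follow, trials)
  expect_equal(res2$fraction_ranked_first[res2$target == "response"],
               c(1, 1))
  # 8-trial handcrafted fixture with one 2-way tie on the stimulus
  tr8 <- data.frame(stimulus = c(1, 2, 3, 4, 1, 2, 3, 4),
                    response = c(1, 2, 3, 4, 2, 1, 4, 3),
                    correct = c(1, 1, 1, 1, 0, 0, 0, 0))
  pr8 <- matrix(0.1, 8, 4)
  pr8[cbind(1:8, tr8$stimulus)] <- 0.7
  pr8[1, ] <- c(0.4, 0.4, 0.1, 0.1)  # 2-way tie, stimulus among the top
  res3 <- error_rank_analysis(pr8, tr8)
  # correct trials, stimulus target: (0.5 + 1 + 1 + 1) / 4
  expect_equal(res3$fraction_ranked_first[res3$target == "stimulus" &
                                            res3$trials == "correct"], 0.875)
  # incorrect trials, response target: never the top -> 0
  expect_equal(res3$fraction_ranked_first[res3$target == "response" &
                                            res3$trials == "incorrect"], 0)
  expect_error(error_rank_analysis(pr8, transform(tr8, response = NA)),
               "missing responses")
})

test_that("error ROC matches the Mann-Whitney statistic and trigram shape", {
  # perfectly separating scores
  tr <- data.frame(stimulus = rep(1L, 10), correct = rep(c(1, 0), each = 5))
  pr <- matrix(0.25, 10, 4)
  pr[, 1] <- c(rep(0.9, 5), rep(0.1, 5))
  pr <- pr / rowSums(pr)
  expect_equal(error_roc(pr, tr)$auc, 1)

  # random fixtures: AUC equals pairwise comparisons with ties counted 1/2
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    tr <- data.frame(stimulus = sample(1:4, n, TRUE),
                     correct = sample(0:1, n, TRUE, prob = c(0.3, 0.7)))
    pr <- matrix(stats::rgamma(4 * n, 1), n, 4)
    pr[sample(n, 5), ] <- 1  # inject ties
    pr <- pr / rowSums(pr)
    score <- pr[cbind(1:n, tr$stimulus)]
    pos <- score[tr$correct == 1]; neg <- score[tr$correct == 0]
    mw <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(error_roc(pr, tr)$auc, mw, tolerance = 1e-12)
  }

  # the trigram model yields exactly two interior ROC points
  s <- generate_session(default_pattern(), n_blocks = 3, seed = 22)
  tg <- trigram_predictions(s)
  tr <- data.frame(stimulus = s$trials$stimulus,
                   correct = rep_len(c(1, 1, 1, 0), nrow(s$trials)))
  pts <- error_roc(tg$predictions, tr)$points
  interior <- pts[!(pts$fpr %in% c(0, 1) & pts$tpr %in% c(0, 1)), ]
  expect_equal(nrow(interior), 2)
  expect_error(error_roc(tg$predictions, transform(tr, correct = 1)), "both")
})

test_that("higher-order score is zero for the trigram model and sign-consistent", {
  pat <- default_pattern()
  s <- generate_session(pat, n_blocks = 10, seed = 31)
  # an ideal-observer participant: pattern trials predicted sharply
  io <- soften_io <- ideal_observer(pat)
  sp <- synthetic_participant(cogtomo:::soften_hmm(io, 0.02, 0.05),
                              later_params(0.18, 8, 0.5))
  trl <- simulate_participant(sp, s, seed = 32)
  cfg <- fit_config(train_blocks = integer(0), test_blocks = 1:10)

  # trigram-model predictions: identical within matched triplets -> exactly 0
  tg <- trigram_predictions(s)
  p_tg <- tg$predictions[cbind(seq_len(nrow(trl)), trl$stimulus)]
  rt_tg <- map_rt(p_tg, later_params(0.18, 8, 2))
  score_tg <- higher_order_score(trl, rts = rt_tg, labels = tg$labels,
                                 config = cfg)
  expect_equal(score_tg, 0)

  # measured RTs of a latent-state-tracking participant: pattern advantage
  score_io <- higher_order_score(trl, labels = tg$labels, config = cfg)
  expect_gt(score_io, 0)

  # relabeling pattern<->random thirds negates the score
  swapped <- trl
  swapped$trial_type <- c(pattern = "random", random = "pattern",
                          warmup = "warmup")[trl$trial_type]
  expect_equal(higher_order_score(swapped, labels = tg$labels, config = cfg),
               -score_io, tolerance = 1e-10)
})

test_that("normalized performance and linear decomposition are exact", {
  expect_equal(normalized_ct(0.3, 0.1), 0.2)
  expect_equal(normalized_ct(c(0.5, 0.2), c(0.5, 0.1)), c(0, 0.1))

  set.seed(41)
  markov <- stats::rnorm(200)
  ideal <- stats::rnorm(200)
  ct <- 0.5 * markov + 0.5 * ideal + 10
  dec <- decompose_ct(ct, markov, ideal)
  expect_equal(unname(dec$weights), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(dec$offset, 10, tolerance = 1e-10)
  expect_equal(dec$r2, 1)

  # independent noise: no fit
  dec0 <- decompose_ct(stats::rnorm(1000), stats::rnorm(1000),
                       stats::rnorm(1000))
  expect_lt(dec0$r2, 0.05)

  # hand-solved 4-point system: ct = 2*markov + 0*ideal + 1
  m4 <- c(0, 1, 2, 3); i4 <- c(1, 0, 1, 0); c4 <- 2 * m4 + 1
  dec4 <- decompose_ct(c4, m4, i4)
  expect_equal(unname(dec4$weights), c(2, 0), tolerance = 1e-10)
  expect_equal(dec4$offset, 1, tolerance = 1e-10)

  expect_error(decompose_ct(c4, m4, 2 * m4 + 5), "condition number")
})
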