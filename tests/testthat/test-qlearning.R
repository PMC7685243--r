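test_that("the TD update changes exactly the taken action's value, by direct evaluation", {
  p <- q_params(alpha = 1, gamma = 0, beta = 1, tau_q = 1)
  q <- rep(0, 10)
  q2 <- q_update(q, 3L, 1, c(7L, 8L), p)
  expect_equal(q2[3], 1)              # full-step update
  expect_equal(q2[-3], rep(0, 9))
  # direct evaluation at the fitted parameters
  p2 <- q_params()                    # alpha 0.81, gamma 0.201
  q3 <- q_update(rep(0, 10), 5L, 1, c(7L, 8L), p2)
  expect_equal(q3[5], 0.81)
  # bootstrap through the successor state's best value
  qq <- rep(0, 10); qq[7] <- 0.5
  q4 <- q_update(qq, 5L, 1, c(7L, 8L), p2)
  expect_equal(q4[5], 0.81 * (1 + 0.201 * 0.5))
  # terminal transition bootstraps zero
  q5 <- q_update(qq, 7L, 1, NULL, p2)
  expect_equal(q5[7], 0.5 + 0.81 * (1 - 0.5))
  # zero learning rate: no change for any reward
  p0 <- q_params(alpha = 1e-12)
  expect_equal(q_update(qq, 5L, 1, c(7L, 8L), p0), qq, tolerance = 1e-10)
  expect_error(q_params(alpha = 2), "alpha")
})

test_that("value decay is multiplicative and composes as tau^n", {
  p <- q_params()
  q <- rep(1, 10)
  expect_equal(q_decay(q, p), rep(0.95, 10))
  expect_equal(q_decay(q, q_params(tau_q = 1)), q)
  qn <- q
  for (i in 1:10) qn <- q_decay(qn, p)
  expect_equal(qn, q * 0.95^10)
})

test_that("softmax choice probabilities behave as the closed form dictates", {
  p <- q_params()
  q <- rep(0, 10)
  expect_equal(unname(choice_probs(q, c(1L, 2L), p)), c(0.5, 0.5))
  # scalar evaluation: Q = (0.81, 0), beta = 3.05
  q[1] <- 0.81
  pr <- choice_probs(q, c(1L, 2L), p)
  expect_equal(unname(pr[1]), exp(3.05 * 0.81) / (exp(3.05 * 0.81) + 1),
               tolerance = 1e-12)
  expect_equal(unname(pr[1]), 0.922, tolerance = 1e-3)
  # beta -> 0 limit: uniform regardless of values
  pr0 <- choice_probs(q * 50, c(1L, 2L), q_params(beta = 1e-10))
  expect_equal(unname(pr0), c(0.5, 0.5), tolerance = 1e-6)
  # invariance to adding a constant to all values
  set.seed(4)
  for (i in 1:20) {
    qq <- rnorm(10)
    expect_equal(choice_probs(qq, c(3L, 4L), p),
                 choice_probs(qq + rnorm(1), c(3L, 4L), p), tolerance = 1e-12)
  }
  expect_error(choice_probs(q, integer(0), p), "empty")
})

test_that("values stay in [0, 1/(1-gamma)] for any behavior stream", {
  set.seed(5)
  log <- simulate_session(30)
  tr <- generate_value_traces(log, q_params())
  bound <- 1 / (1 - 0.201)
  expect_true(all(tr$post >= 0 - 1e-12))
  expect_true(all(tr$post <= bound + 1e-12))
})

test_that("value traces rise with rewarded repetitions and decay after errors", {
  p <- q_params()
  # a hand-built log: one block of S5 played perfectly
  st <- new_block(); sid <- st$sequence_id <- 5L
  rows <- list(); st0 <- st
  while (TRUE) {
    a <- seq_moves(sid)[st0$stage + 1]
    res <- task_step(st0, a)
    rows[[length(rows) + 1]] <- data.frame(
      block_id = 1L, trial_index = st0$trial_index, stage = st0$stage,
      sequence_id = sid, action_id = a, reward = res$outcome$reward,
      correct = TRUE, repeat_flag = FALSE)
    if (res$outcome$block_done) break
    st0 <- res$state
  }
  log <- do.call(rbind, rows)
  tr <- generate_value_traces(log, p)
  # value of each correct direction strictly increases over the first
  # consecutive rewarded repetitions
  for (stage in 0:2) {
    idx <- which(log$stage == stage)
    a <- log$action_id[idx[1]]
    vals <- tr$post[idx, a]
    expect_true(all(diff(vals[1:4]) > 0))
  }
  # an unrewarded wrong move decays towards zero afterwards
  log2 <- simulate_session(20, q_params())
  tr2 <- generate_value_traces(log2, p)
  wrong <- which(!log2$correct)
  if (length(wrong)) {
    i <- wrong[1]; a <- log2$action_id[i]
    expect_lte(tr2$post[i, a], tr2$pre[i, a])
  }
  # replay is pure: same log, same traces, bit for bit
  expect_identical(tr$post, generate_value_traces(log, p)$post)
  # empty log
  e <- generate_value_traces(log[0, ], p)
  expect_equal(nrow(e$post), 0L)
})

test_that("maximum likelihood fitting recovers the generating parameters", {
  set.seed(6)
  truth <- q_params(alpha = 0.8, gamma = 0.2, beta = 3.0)
  log <- simulate_session(300, truth)
  fit <- fit_qlearning(log, n_restarts = 4L)
  expect_s3_class(fit, "qfit")
  expect_lt(abs(fit$params$alpha - 0.8), 0.15)
  expect_lt(abs(fit$params$beta - 3.0), 0.5)
  expect_equal(fit$params$tau_q, 0.95)   # held fixed
  # the fitted optimum beats random perturbations around it (the log is
  # compiled once; replaying it per perturbation would dominate runtime)
  nll_hat <- qlearning_nll(log, fit$params)
  expect_equal(nll_hat, fit$nll, tolerance = 1e-6)
  cl <- striatnet:::compile_log(log)
  for (i in 1:50) {
    pert <- c(
      alpha = min(0.999, max(0.01, fit$params$alpha + rnorm(1, 0, 0.05))),
      gamma = min(0.99, max(0, fit$params$gamma + rnorm(1, 0, 0.05))),
      beta = max(0.1, fit$params$beta + rnorm(1, 0, 0.2)),
      tau_q = 0.95)
    expect_lte(nll_hat, striatnet:::qlearn_nll(pert, cl) + 1e-6)
  }
  expect_error(fit_qlearning(log[0, ]), "empty")
  expect_error(fit_qlearning(log[1:10, ]), "at least 50")
})
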