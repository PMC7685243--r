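make_block_log <- function(sid, n_trials = 1L, errors = integer(0)) {
  # play `n_trials` trials of sequence sid, inserting one error before the
  # decisions whose global index is in `errors`
  st <- new_block(); st$sequence_id <- sid
  rows <- list(); k <- 0L
  while (st$correct_trials_in_block < n_trials) {
    correct_a <- seq_moves(sid)[st$stage + 1]
    k <- k + 1L
    if (k %in% errors && !st$pending_repeat) {
      a <- setdiff(available_actions(st), correct_a)
    } else {
      a <- correct_a
    }
    res <- task_step(st, a)
    rows[[length(rows) + 1]] <- data.frame(
      block_id = 1L, trial_index = st$trial_index, stage = st$stage,
      sequence_id = sid, action_id = a, reward = res$outcome$reward,
      correct = res$outcome$correct, repeat_flag = st$pending_repeat)
    if (res$outcome$block_done) break
    st <- res$state
  }
  do.call(rbind, rows)
}

encode_with_traces <- function(log, cfg) {
  tr <- generate_value_traces(log, q_params())
  encode_block(log, tr, cfg)
}

test_that("the coding config enforces the 2/10 reward-to-action pulse ratio", {
  cfg <- coding_config(action_pulse_len = 50)
  expect_equal(cfg$reward_pulse_len, 10L)
  expect_equal(coding_config(action_pulse_len = 15)$reward_pulse_len, 3L)
  expect_equal(cfg$seg_len, 50L + 10L + 10L)
})

test_that("a perfect S5 trial produces pulses on exactly its three direction channels", {
  set.seed(12)
  cfg <- coding_config(action_pulse_len = 10, gap = 4)
  log <- make_block_log(5L, n_trials = 1L)
  enc <- encode_with_traces(log, cfg)
  L <- cfg$seg_len
  expect_equal(nrow(enc$u_s), 4L * L)    # 3 decisions + opening segment
  # action pulses on channels center-R (2), right-up (5), upper-R (8)
  on <- which(colSums(enc$u_s[-(1:L), 1:10] == 1) > 0)
  expect_equal(on, c(2L, 5L, 8L))
  # three reward pulses, one per decision, on the right decision points
  expect_equal(sum(enc$u_s[, 11:15]), 3 * cfg$reward_pulse_len)
  rew_on <- which(colSums(enc$u_s[, 11:15]) > 0)
  expect_equal(rew_on, c(1L, 2L, 4L))    # center, upwards, upper
  # reward pulse begins exactly at the end of its action pulse
  d1 <- L + cfg$gap + cfg$action_pulse_len
  expect_equal(enc$u_s[d1, 10 + 1], 0)
  expect_equal(enc$u_s[d1 + 1, 10 + 1], 1)
  # channels of other directions stay flat
  expect_true(all(enc$u_s[, setdiff(1:10, c(2, 5, 8))] == 0 |
                    seq_len(nrow(enc$u_s)) <= L))
  # hemifield unit: S5 ends upper
  expect_true(all(enc$y_a[, 11] == 1))
})

test_that("error decisions carry an action pulse but no reward", {
  set.seed(13)
  cfg <- coding_config(action_pulse_len = 10, gap = 4)
  log <- make_block_log(5L, n_trials = 2L, errors = 1L)
  expect_false(log$correct[1])
  enc <- encode_with_traces(log, cfg)
  L <- cfg$seg_len
  seg1 <- L + seq_len(L)                  # segment replaying decision 1
  wrong_ch <- log$action_id[1]
  expect_equal(sum(enc$u_s[seg1, wrong_ch]), cfg$action_pulse_len)
  expect_equal(sum(enc$u_s[seg1, 11:15]), 0)
  # per-trial reward-channel mass equals the number of rewarded decisions
  for (tr in unique(log$trial_index)) {
    d <- which(log$trial_index == tr)
    rows <- unlist(lapply(d, function(i) i * L + seq_len(L)))
    expect_equal(sum(enc$u_s[rows, 11:15]) / cfg$reward_pulse_len,
                 sum(log$reward[d]))
  }
})

test_that("round-trip: peak action channels recover the logged action sequence", {
  set.seed(14)
  cfg <- coding_config(action_pulse_len = 8, gap = 3)
  log <- simulate_session(3)
  tr <- generate_value_traces(log, q_params())
  for (b in unique(log$block_id)) {
    rows <- which(log$block_id == b)
    enc <- encode_block(log[rows, ], list(pre = tr$pre[rows, , drop = FALSE],
                                          post = tr$post[rows, , drop = FALSE]),
                        cfg)
    L <- cfg$seg_len
    decoded <- vapply(seq_along(rows), function(d) {
      seg_rows <- d * L + cfg$gap + seq_len(cfg$action_pulse_len)
      which.max(colSums(enc$u_s[seg_rows, 1:10]))
    }, integer(1))
    expect_equal(decoded, log$action_id[rows])
  }
})

test_that("value targets step up at reward onset, matching the Q trace", {
  set.seed(15)
  cfg <- coding_config(action_pulse_len = 10, gap = 4)
  log <- make_block_log(5L, n_trials = 3L)
  tr <- generate_value_traces(log, q_params())
  enc <- encode_block(log, tr, cfg)
  L <- cfg$seg_len
  for (d in seq_len(nrow(log))) {
    pre_rows <- d * L + seq_len(cfg$gap + cfg$action_pulse_len)
    post_rows <- d * L + cfg$gap + cfg$action_pulse_len +
      seq_len(cfg$reward_pulse_len)
    expect_equal(enc$y_v[pre_rows[1], ], tr$pre[d, ])
    expect_equal(enc$y_v[post_rows[1], ], tr$post[d, ])
  }
})

test_that("empty blocks encode to zero-length tensors and bad ids error", {
  cfg <- coding_config()
  e <- encode_block(data.frame(), list(pre = matrix(0, 0, 10),
                                       post = matrix(0, 0, 10)), cfg)
  expect_equal(nrow(e$u_s), 0L)
  bad <- make_block_log(1L, 1L); bad$action_id[1] <- 11L
  expect_error(encode_block(bad, generate_value_traces(make_block_log(1L, 1L),
                                                       q_params()), cfg),
               "vocabulary")
})

test_that("train/test split is disjoint at block granularity; augmentation feeds train only", {
  set.seed(16)
  log <- simulate_session(100)
  cfg <- coding_config(action_pulse_len = 5, gap = 2)
  ds <- build_dataset(log, cfg = cfg, test_blocks = 25)
  expect_length(ds$test, 25L)
  expect_length(ds$train, 75L)
  expect_length(intersect(ds$train_ids, ds$test_ids), 0L)
  aug <- simulate_session(10)
  ds2 <- build_dataset(log, cfg = cfg, test_blocks = 25, augment = aug)
  expect_length(ds2$train, 85L)
  expect_length(ds2$test, 25L)
  set.seed(99); a <- build_dataset(log, cfg = cfg)$test_ids
  set.seed(99); b <- build_dataset(log, cfg = cfg)$test_ids
  expect_identical(a, b)
  expect_error(build_dataset(log[log$block_id <= 20, ], cfg = cfg,
                             test_blocks = 25), "blocks")
})

test_that("batches are drawn uniformly with replacement across the training set", {
  set.seed(17)
  train <- as.list(1:20)   # sample_batch only indexes, content is irrelevant
  b <- sample_batch(train, 10L)
  expect_length(b, 10L)
  expect_identical(sample_batch(list("x"), 1L), list("x"))
  draws <- unlist(replicate(2000, sample_batch(train, 1L)))
  freq <- table(factor(draws, levels = 1:20)) / 2000
  expect_true(all(abs(freq - 1 / 20) < 4 * sqrt(0.05 * 0.95 / 2000)))
  expect_error(sample_batch(list(), 3L), "empty")
})
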