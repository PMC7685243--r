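test_that("the sequence table has the required structure", {
  tab <- task_sequences()
  expect_equal(nrow(tab), 8L)
  expect_equal(sort(tab$id), 1:8)
  moves <- as.matrix(tab[, c("m1", "m2", "m3")])
  expect_true(all(moves %in% 1:10))
  # every direction occurs in at least two sequences
  expect_true(all(table(factor(moves, levels = 1:10)) >= 2))
  # hemifield partition: S1, S2, S5, S6 upper; S3, S4, S7, S8 lower
  expect_equal(tab$hemifield[tab$id %in% c(1, 2, 5, 6)], rep("upper", 4))
  expect_equal(tab$hemifield[tab$id %in% c(3, 4, 7, 8)], rep("lower", 4))
  # the third move's hemifield matches the label
  expect_true(all((tab$m3 %in% 7:8) == (tab$hemifield == "upper")))
})

test_that("new-block draws are uniform, and exclusion removes the previous sequence", {
  set.seed(1)
  n <- 40000L
  draws <- vapply(seq_len(n), function(i) new_block()$sequence_id, integer(1))
  freq <- tabulate(draws, 8L) / n
  se <- sqrt((1 / 8) * (7 / 8) / n)
  expect_true(all(abs(freq - 1 / 8) < 3.5 * se))
  excl <- vapply(seq_len(3000L), function(i) {
    new_block(prev = 3L, allow_repeat = FALSE)$sequence_id
  }, integer(1))
  expect_false(any(excl == 3L))
  st <- new_block()
  expect_equal(st$stage, 0L)
  expect_equal(st$correct_trials_in_block, 0L)
  expect_error(new_block(prev = 99L, allow_repeat = FALSE), "unknown")
})

test_that("exactly two actions are available at every reachable state", {
  for (sid in 1:8) {
    st <- new_block()
    st$sequence_id <- sid
    moves <- unlist(task_sequences()[sid, c("m1", "m2", "m3")])
    for (stage in 0:2) {
      av <- available_actions(st)
      expect_length(av, 2L)
      expect_true(moves[stage + 1] %in% av)
      if (stage == 0L) expect_equal(sort(av), c(1L, 2L))
      st <- task_step(st, moves[stage + 1])$state
    }
  }
  # upper-hemifield sequences: the lower-hemifield options are unavailable
  # at the final movement stage
  for (sid in c(1L, 5L)) {
    st <- new_block()
    st$sequence_id <- sid
    st <- task_step(st, seq_moves(sid)[1])$state
    st <- task_step(st, seq_moves(sid)[2])$state
    expect_true(all(available_actions(st) %in% 7:8))
  }
  st <- new_block(); st$stage <- 7L
  expect_error(available_actions(st), "invalid stage")
})

test_that("stepping follows the reward / repeat / block-termination rules", {
  st <- new_block()
  st$sequence_id <- 5L   # center-R, right-up, upper-R
  mv <- seq_moves(5L)
  # wrong action: no reward, same stage again, repeat pending
  wrong <- setdiff(available_actions(st), mv[1])
  res <- task_step(st, wrong)
  expect_equal(res$outcome$reward, 0L)
  expect_false(res$outcome$correct)
  expect_equal(res$state$stage, 0L)
  expect_true(res$state$pending_repeat)
  # completing the trial after an error does not count towards the block
  st2 <- res$state
  for (m in mv) st2 <- task_step(st2, m)$state
  expect_equal(st2$correct_trials_in_block, 0L)
  expect_equal(st2$trial_index, 2L)
  # an error-free trial counts
  for (m in mv) st2 <- task_step(st2, m)$state
  expect_equal(st2$correct_trials_in_block, 1L)
  expect_error(task_step(st, 9L), "not available")
})

test_that("a perfect policy finishes in 24 rewarded decisions; errors never count", {
  set.seed(2)
  for (rep in 1:8) {
    p_err <- c(0, 0.3)[(rep %% 2) + 1]
    st <- new_block()
    mv <- seq_moves(st$sequence_id)
    steps <- 0L; rewards <- 0L; clean_trials <- 0L; trial_clean <- TRUE
    repeat {
      correct_a <- mv[st$stage + 1]
      a <- if (runif(1) < p_err) setdiff(available_actions(st), correct_a) else correct_a
      res <- task_step(st, a)
      steps <- steps + 1L
      rewards <- rewards + res$outcome$reward
      if (!res$outcome$correct) trial_clean <- FALSE
      if (res$outcome$trial_done) {
        if (trial_clean) clean_trials <- clean_trials + 1L
        trial_clean <- TRUE
      }
      if (res$outcome$block_done) break
      st <- res$state
    }
    expect_equal(clean_trials, 8L)
    if (p_err == 0) {
      expect_equal(steps, 24L)
      expect_equal(rewards, 24L)
    } else {
      expect_gte(steps, 24L)
    }
  }
})

test_that("the forced-repeat guard bounds infinite error loops", {
  st <- new_block(max_repeat = 3L)
  wrong <- setdiff(available_actions(st), seq_moves(st$sequence_id)[1])
  for (i in 1:3) st <- task_step(st, wrong)$state
  expect_error(task_step(st, wrong), "max_repeat")
})

test_that("trial logs validate, round-trip through CSV, and tampering is caught", {
  set.seed(3)
  log <- simulate_session(5)
  expect_true(validate_trial_log(log))
  path <- tempfile(fileext = ".csv")
  write_trial_log(log, path)
  expect_equal(read_trial_log(path), log)
  bad <- log
  bad$reward[4] <- 1L - bad$reward[4]
  expect_error(validate_trial_log(bad), "mismatch")
})
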