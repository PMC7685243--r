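## Synthetic behavior: a Q-learning agent (or a parametric error profile)
## playing the sequence task, standing in for the monkey choice data. The
## generator reproduces the animals' learning curve: ~50% correct on the
## first decision of a block rising to ~90% by the fifth trial.

#' Simulate a session of task blocks
#'
#' Generates a behavior log either from a Q-learning agent interacting with
#' the task (\code{mode = "q_agent"}, the default, using the fitted monkey
#' parameters) or by drawing the correctness of every first-attempt decision
#' from a per-trial-in-block probability profile (\code{mode =
#' "parametric"}). Action values are carried across blocks in q_agent mode,
#' so that the start-of-block error rate reflects the decayed values of the
#' previous block's sequence.
#'
#' @param n_blocks Number of blocks to simulate (>= 1).
#' @param params A \code{\link{q_params}} object (q_agent mode).
#' @param profile Numeric vector of per-trial-in-block probabilities that a
#'   first-attempt decision is correct (parametric mode); trials beyond its
#'   length use the last entry. Forced repeats after an error are always
#'   given the correct action on the second attempt in parametric mode.
#' @param mode \code{"q_agent"} or \code{"parametric"}.
#' @param allow_repeat Passed to \code{\link{new_block}}: may a block reuse
#'   the previous block's sequence?
#' @param max_repeat Safety bound on consecutive errors at one decision.
#' @return A behavior log data.frame with one row per decision and columns
#'   \code{block_id}, \code{trial_index}, \code{stage}, \code{sequence_id},
#'   \code{action_id}, \code{reward}, \code{correct}, \code{repeat_flag}.
#' @export
simulate_session <- function(n_blocks, params = q_params(), profile = NULL,
                             mode = c("q_agent", "parametric"),
                             allow_repeat = TRUE, max_repeat = 50L) {
  mode <- match.arg(mode)
  stopifnot(n_blocks >= 1L)
  if (mode == "q_agent") {
    stopifnot(inherits(params, "q_params"))
  } else {
    if (is.null(profile) || length(profile) < 1L ||
        any(!is.finite(profile)) || any(profile < 0 | profile > 1)) {
      stop("parametric mode needs a probability profile with entries in [0, 1]")
    }
  }
  rows <- vector("list", n_blocks * 40L)
  nr <- 0L
  q <- rep(0, 10)
  prev <- NULL
  for (b in seq_len(n_blocks)) {
    st <- new_block(prev = prev, allow_repeat = allow_repeat,
                    max_repeat = max_repeat)
    prev <- st$sequence_id
    done <- FALSE
    while (!done) {
      avail <- available_actions(st)
      if (mode == "q_agent") {
        p <- choice_probs(q, avail, params)
        action <- avail[sample.int(length(avail), 1L, prob = p)]
      } else {
        correct_move <- seq_moves(st$sequence_id)[st$stage + 1L]
        if (st$pending_repeat) {
          action <- correct_move
        } else {
          pc <- profile[min(st$trial_index, length(profile))]
          action <- if (stats::runif(1) < pc) correct_move
                    else setdiff(avail, correct_move)[1L]
        }
      }
      res <- task_step(st, action)
      nr <- nr + 1L
      rows[[nr]] <- c(b, st$trial_index, st$stage, st$sequence_id, action,
                      res$outcome$reward, as.integer(res$outcome$correct),
                      as.integer(st$pending_repeat))
      if (mode == "q_agent") {
        nxt <- if (res$outcome$trial_done) integer(0)
               else available_actions(res$state)
        q <- q_update(q, action, res$outcome$reward, nxt, params)
        q <- q_decay(q, params)
      }
      done <- res$outcome$block_done
      st <- res$state
    }
  }
  m <- do.call(rbind, rows[seq_len(nr)])
  log <- data.frame(block_id = m[, 1], trial_index = m[, 2], stage = m[, 3],
                    sequence_id = m[, 4], action_id = m[, 5], reward = m[, 6],
                    correct = as.logical(m[, 7]),
                    repeat_flag = as.logical(m[, 8]))
  log
}

#' Empirical learning curve of a behavior log
#'
#' Computes, for each trial-in-block index, the fraction of first-attempt
#' decisions (forced repeats excluded) that were correct, pooled over
#' blocks, with normal-approximation binomial confidence intervals.
#'
#' @param log A behavior log data.frame.
#' @param max_trial Trials with index beyond this are pooled into the last
#'   bin (error trials can push the index past 8).
#' @param conf Confidence level for the intervals.
#' @return An object of class \code{error_profile}: a data.frame with
#'   columns \code{trial}, \code{p_correct}, \code{n}, \code{lo}, \code{hi}.
#' @export
error_profile <- function(log, max_trial = 8L, conf = 0.95) {
  stopifnot(is.data.frame(log), nrow(log) >= 1L)
  first <- log[!log$repeat_flag, , drop = FALSE]
  tr <- pmin(first$trial_index, max_trial)
  n <- tapply(tr, tr, length)
  k <- tapply(first$correct, tr, sum)
  p <- as.numeric(k / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(pmax(p * (1 - p), 0) / as.numeric(n))
  out <- data.frame(trial = as.integer(names(n)), p_correct = p,
                    n = as.integer(n),
                    lo = pmax(0, p - z * se), hi = pmin(1, p + z * se))
  rownames(out) <- NULL
  class(out) <- c("error_profile", "data.frame")
  out
}

#' @export
print.error_profile <- function(x, ...) {
  cat("Fraction of first-attempt-correct decisions by trial in block:\n")
  print.data.frame(cbind(x["trial"],
                         p_correct = round(x$p_correct, 3),
                         n = x$n), row.names = FALSE)
  invisible(x)
}

#' @export
plot.error_profile <- function(x, ...) {
  graphics::plot(x$trial, x$p_correct, type = "b", ylim = c(0, 1),
                 xlab = "trial after sequence switch",
                 ylab = "fraction correct", ...)
  graphics::arrows(x$trial, x$lo, x$trial, x$hi, angle = 90, code = 3,
                   length = 0.03)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Assign certainty levels to trials
#'
#' Labels every trial with one of the three certainty (fraction-correct)
#' levels used throughout the latent-space analyses: ~50\% at the start of
#' the block, ~76\% at intermediate positions, and 88-91\% late in the
#' block. The default mapping is by trial position (trial 1; trials 2-4;
#' trials 5 and later), the positions at which a learner rising from chance
#' to ~90\% by trial 5 passes those levels; \code{by = "empirical"} instead
#' bins each position's empirical fraction-correct to the nearest level.
#'
#' @param log A behavior log data.frame.
#' @param by \code{"position"} (default) or \code{"empirical"}.
#' @param profile Optional precomputed \code{\link{error_profile}}; computed
#'   from \code{log} when missing (used for the reported \code{p_correct}
#'   and for empirical binning).
#' @param levels Numeric certainty levels defining the bins.
#' @param labels Labels for the bins.
#' @return A data.frame with one row per trial: \code{block_id},
#'   \code{trial_index}, \code{p_correct} and factor \code{certainty}.
#' @export
assign_certainty <- function(log, by = c("position", "empirical"),
                             profile = NULL,
                             levels = c(0.50, 0.76, 0.895),
                             labels = c("50%", "76%", "88-91%")) {
  by <- match.arg(by)
  stopifnot(length(levels) == length(labels))
  if (is.null(profile)) profile <- error_profile(log)
  trials <- unique(log[, c("block_id", "trial_index")])
  idx <- pmin(trials$trial_index, max(profile$trial))
  p <- profile$p_correct[match(idx, profile$trial)]
  bin <- if (by == "position") {
    ifelse(trials$trial_index == 1L, 1L,
           ifelse(trials$trial_index <= 4L, 2L, 3L))
  } else {
    vapply(p, function(pi) which.min(abs(pi - levels)), integer(1))
  }
  data.frame(block_id = trials$block_id, trial_index = trials$trial_index,
             p_correct = p,
             certainty = factor(labels[bin], levels = labels))
}
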