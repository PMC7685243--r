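## Autonomous (closed-loop) mode: the prefrontal network's decoded actions
## are fed back into the striatal network together with the rewards the
## environment delivers; all weights are frozen. A block opens with a
## white-noise action segment; wrong decisions force a repeat of the stage
## with the reward channels set to white noise.

#' Decode an action from prefrontal output
#'
#' Restricts the 10 action-channel outputs to the actions available at the
#' current movement stage, passes them through a softmax, and samples the
#' choice. The hemifield unit (channel 11) is ignored.
#'
#' The default inverse temperature is the fitted behavioral one
#' (beta = 3.05): the prefrontal network is trained on stochastically
#' chosen actions, so its output amplitudes approximate choice
#' \emph{probabilities} (the conditional mean of a one-hot draw), and
#' passing probability-valued outputs through a unit-temperature softmax
#' would cap attainable accuracy at plogis(1) ~ 0.73 regardless of
#' training. Reading them out with the same inverse temperature that
#' generated the behavior reproduces the behavioral learning curve.
#'
#' @param u_a Numeric vector of the 10 action-channel outputs (or 11, in
#'   which case the last entry is dropped).
#' @param available Integer vector of available direction ids.
#' @param beta Softmax inverse temperature for decoding.
#' @return The sampled direction id.
#' @export
decode_action <- function(u_a, available, beta = q_params()$beta) {
  if (length(available) == 0L) stop("empty set of available actions")
  if (length(u_a) == 11L) u_a <- u_a[1:10]
  stopifnot(length(u_a) == 10L, beta > 0)
  z <- beta * u_a[available]
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  available[sample.int(length(available), 1L, prob = p)]
}

## build the input tensors of one segment: the action content (a direction
## pulse, or white noise for a block opener), the reward content (pulse /
## zeros / white noise), and the instructions of the upcoming decision.
segment_inputs <- function(cfg, action = NULL, reward_point = NULL,
                           reward_noise = FALSE, upcoming_stage = NULL,
                           hemifield = NULL) {
  L <- cfg$seg_len
  u_s <- matrix(0, L, 15)
  u_ins <- matrix(0, L, 10)
  fix_rows <- seq_len(cfg$gap)
  act_rows <- cfg$gap + seq_len(cfg$action_pulse_len)
  rew_rows <- cfg$gap + cfg$action_pulse_len + seq_len(cfg$reward_pulse_len)
  if (is.null(action)) {
    u_s[act_rows, 1:10] <- stats::rnorm(length(act_rows) * 10L, 0, cfg$noise_sd)
  } else {
    u_s[act_rows, action] <- 1
  }
  if (!is.null(reward_point)) {
    u_s[rew_rows, 10L + reward_point] <- 1
  } else if (reward_noise) {
    u_s[rew_rows, 11:15] <- stats::rnorm(length(rew_rows) * 5L, 0, cfg$noise_sd)
  }
  if (!is.null(upcoming_stage)) {
    pts <- instruction_points(upcoming_stage, hemifield)
    u_ins[fix_rows, 2L * pts - 1L] <- 1
    u_ins[act_rows, 2L * pts] <- 1
  }
  list(u_s = u_s, u_ins = u_ins, act_rows = act_rows)
}

#' Run the trained system in closed loop
#'
#' Produces whole blocks autonomously: each segment feeds the previous
#' decision (action pulse + reward pulse, or white-noise rewards after an
#' error) into the striatal network, whose value readout drives the
#' prefrontal network together with the upcoming stage's instructions; the
#' action for the next decision is decoded from the prefrontal output over
#' the action epoch and applied to the task environment. Synaptic currents
#' are carried across segments; by default they are reset to zero at block
#' boundaries, matching the state distribution the network was trained
#' under (each training block is rolled out from zero currents).
#'
#' @param net A trained \code{corticostriatal_net}.
#' @param n_blocks Number of blocks to produce.
#' @param cfg The \code{\link{coding_config}} the network was trained with.
#' @param allow_repeat,max_repeat Passed to \code{\link{new_block}}.
#' @param noise Inject unit noise during rollouts (the trained operating
#'   regime)?
#' @param record_states Keep the full synaptic-current traces of every
#'   block (needed for population analyses; memory-heavy)?
#' @param reset_state Reset synaptic currents to zero at block boundaries
#'   (the training distribution)? Set \code{FALSE} for a fully continuous
#'   session.
#' @param decode_beta Softmax inverse temperature of the action decoder
#'   (see \code{\link{decode_action}}).
#' @return An object of class \code{autonomous_run}: the behavior
#'   \code{log} (standard schema), and per-block readout traces
#'   \code{blocks[[b]]$u_v}, \code{$u_a}, segment table, and (optionally)
#'   current matrices \code{x_s}, \code{x_p}.
#' @export
run_autonomous <- function(net, n_blocks, cfg = coding_config(),
                           allow_repeat = TRUE, max_repeat = 50L,
                           noise = TRUE, record_states = FALSE,
                           reset_state = TRUE,
                           decode_beta = q_params()$beta) {
  stopifnot(inherits(net, "corticostriatal_net"), n_blocks >= 1L)
  x_s <- rep(0, net$n_s); x_p <- rep(0, net$n_p)
  logs <- list(); blocks <- list()
  prev <- NULL
  for (b in seq_len(n_blocks)) {
    if (reset_state) {
      x_s <- rep(0, net$n_s); x_p <- rep(0, net$n_p)
    }
    st <- new_block(prev = prev, allow_repeat = allow_repeat,
                    max_repeat = max_repeat)
    prev <- st$sequence_id
    hemi <- task_sequences()$hemifield[task_sequences()$id == st$sequence_id]
    seg_list <- list(); seg_meta <- list()
    rows <- list()
    pending <- list(action = NULL, reward_point = NULL, reward_noise = FALSE)
    done <- FALSE
    seg_i <- 0L
    decided <- 0L
    while (!done) {
      seg <- segment_inputs(cfg, action = pending$action,
                            reward_point = pending$reward_point,
                            reward_noise = pending$reward_noise,
                            upcoming_stage = st$stage, hemifield = hemi)
      out <- net_rollout(net, seg, x0_s = x_s, x0_p = x_p, noise = noise,
                         record_states = record_states)
      x_s <- drop(out$x_end_s); x_p <- drop(out$x_end_p)
      avail <- available_actions(st)
      act_mean <- colMeans(out$u_a[seg$act_rows, 1:10, drop = FALSE])
      action <- decode_action(act_mean, avail, beta = decode_beta)
      res <- task_step(st, action)
      decided <- decided + 1L
      rows[[decided]] <- c(b, st$trial_index, st$stage, st$sequence_id,
                           action, res$outcome$reward,
                           as.integer(res$outcome$correct),
                           as.integer(st$pending_repeat))
      seg_i <- seg_i + 1L
      seg_list[[seg_i]] <- list(u_v = out$u_v, u_a = out$u_a,
                                x_s = out$x_s, x_p = out$x_p)
      seg_meta[[seg_i]] <- data.frame(
        segment = seg_i - 1L, decodes_decision = decided,
        trial_index = st$trial_index, stage = st$stage,
        repeat_flag = rows[[decided]][8] == 1)
      if (res$outcome$correct) {
        pending <- list(action = action,
                        reward_point = decision_point_of(st$stage, action),
                        reward_noise = FALSE)
      } else {
        pending <- list(action = action, reward_point = NULL,
                        reward_noise = TRUE)
      }
      done <- res$outcome$block_done
      st <- res$state
    }
    ## closing segment: replay the final rewarded decision, no decode
    seg <- segment_inputs(cfg, action = pending$action,
                          reward_point = pending$reward_point,
                          reward_noise = pending$reward_noise,
                          upcoming_stage = NULL, hemifield = hemi)
    out <- net_rollout(net, seg, x0_s = x_s, x0_p = x_p, noise = noise,
                       record_states = record_states)
    x_s <- drop(out$x_end_s); x_p <- drop(out$x_end_p)
    seg_i <- seg_i + 1L
    seg_list[[seg_i]] <- list(u_v = out$u_v, u_a = out$u_a,
                              x_s = out$x_s, x_p = out$x_p)
    seg_meta[[seg_i]] <- data.frame(segment = seg_i - 1L,
                                    decodes_decision = NA_integer_,
                                    trial_index = NA_integer_,
                                    stage = NA_integer_, repeat_flag = FALSE)
    m <- do.call(rbind, rows)
    blocks[[b]] <- list(
      sequence_id = m[1, 4], hemifield = hemi,
      u_v = do.call(rbind, lapply(seg_list, `[[`, "u_v")),
      u_a = do.call(rbind, lapply(seg_list, `[[`, "u_a")),
      x_s = if (record_states) do.call(rbind, lapply(seg_list, `[[`, "x_s")),
      x_p = if (record_states) do.call(rbind, lapply(seg_list, `[[`, "x_p")),
      segments = do.call(rbind, seg_meta))
    logs[[b]] <- m
  }
  m <- do.call(rbind, logs)
  log <- data.frame(block_id = m[, 1], trial_index = m[, 2], stage = m[, 3],
                    sequence_id = m[, 4], action_id = m[, 5], reward = m[, 6],
                    correct = as.logical(m[, 7]),
                    repeat_flag = as.logical(m[, 8]))
  structure(list(log = log, blocks = blocks, cfg = cfg,
                 record_states = record_states),
            class = "autonomous_run")
}

#' @export
print.autonomous_run <- function(x, ...) {
  nb <- length(x$blocks)
  cat(sprintf("<autonomous_run> %d blocks, %d decisions, %.1f%% correct (first attempts)\n",
              nb, nrow(x$log),
              100 * mean(x$log$correct[!x$log$repeat_flag])))
  invisible(x)
}

#' Behavioral learning curve of closed-loop runs
#'
#' Fraction of first-attempt-correct decisions by trial-in-block, the same
#' statistic as \code{\link{error_profile}} computed on model behavior.
#'
#' @param run An \code{autonomous_run} (or its behavior log).
#' @param min_blocks Minimum number of blocks required.
#' @return An \code{\link{error_profile}}.
#' @export
behavioral_curve <- function(run, min_blocks = 10L) {
  log <- if (inherits(run, "autonomous_run")) run$log else run
  if (length(unique(log$block_id)) < min_blocks) {
    stop("need at least ", min_blocks, " blocks")
  }
  error_profile(log)
}

#' @export
simulate.corticostriatal_net <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  run_autonomous(object, n_blocks = nsim, ...)
}
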