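## Task environment: deterministic state machine for the oculomotor
## sequence task. Eight sequences of three saccades, blocks of eight
## error-free trials, forced repeats after errors.

.task_cache <- new.env(parent = emptyenv())

#' Canonical movement-direction vocabulary
#'
#' The ten movement directions of the task, in the canonical ordering used
#' by every 10-dimensional vector in the package (action inputs, action
#' outputs, action values). The first binary decision is made at the central
#' fixation point (left/right), the second at the chosen side (up/down), and
#' the third along the top or bottom of the display (left/right).
#'
#' @return Character vector of length 10; positions are the direction ids.
#' @export
task_directions <- function() {
  c("center-L", "center-R",
    "left-up", "left-down", "right-up", "right-down",
    "upper-L", "upper-R", "lower-L", "lower-R")
}

#' Decision-point labels
#'
#' The five points at which a binary decision is made and at which a reward
#' can be delivered: the central fixation point, the upwards/downwards
#' saccade of the second movement, and the upper/lower hemifield of the
#' third movement.
#'
#' @return Character vector of length 5.
#' @export
decision_points <- function() {
  c("center", "upwards", "downwards", "upper", "lower")
}

#' The eight movement sequences
#'
#' Every trial is a sequence of three binary decisions, so exactly eight
#' ordered triples of movement directions exist. Sequences S1, S2, S5 and S6
#' terminate in the upper visual hemifield; S3, S4, S7 and S8 in the lower.
#' The table is shipped as a JSON resource (\code{extdata/sequences.json}).
#' Which of the four upper (lower) paths carries which id is not observable
#' from aggregate statistics; the assignment used here is a fixed canonical
#' one consistent with the hemifield partition.
#'
#' @return A data.frame with columns \code{id}, \code{m1}, \code{m2},
#'   \code{m3} (direction ids of the three movements) and \code{hemifield}
#'   (\code{"upper"} or \code{"lower"}).
#' @export
task_sequences <- function() {
  if (!is.null(.task_cache$sequences)) return(.task_cache$sequences)
  path <- system.file("extdata", "sequences.json", package = "striatnet")
  tab <- as.data.frame(jsonlite::fromJSON(path))
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  stopifnot(nrow(tab) == 8L, all(tab$hemifield %in% c("upper", "lower")))
  .task_cache$sequences <- tab
  tab
}

seq_moves <- function(seq_id) {
  tab <- task_sequences()
  unlist(tab[tab$id == seq_id, c("m1", "m2", "m3")], use.names = FALSE)
}

#' Start a new block
#'
#' Draws the block's correct sequence pseudorandomly and uniformly from the
#' eight sequences. By default the previous block's sequence is \emph{not}
#' excluded from the draw: a uniform draw over all eight is the only rule
#' under which a value-carrying agent is at exactly 50\% on the first
#' decision after a switch (by left/right symmetry), matching the observed
#' chance-level behavior at the start of a block. Set
#' \code{allow_repeat = FALSE} to force a genuine switch on every block.
#' Uses R's global random number stream.
#'
#' @param prev Sequence id of the previous block, or \code{NULL}.
#' @param allow_repeat Logical; if \code{FALSE}, \code{prev} is excluded
#'   from the draw.
#' @param max_repeat Safety bound on consecutive forced repeats of a single
#'   decision before an error is thrown (keeps simulations finite).
#' @return A \code{task_state} object: the block's sequence id, current
#'   stage (0-2), number of error-free trials completed, trial index, and
#'   repeat-tracking flags.
#' @export
new_block <- function(prev = NULL, allow_repeat = TRUE, max_repeat = 50L) {
  ids <- task_sequences()$id
  if (!is.null(prev) && !allow_repeat) {
    if (!prev %in% ids) stop("unknown previous sequence id: ", prev)
    ids <- setdiff(ids, prev)
  }
  sid <- ids[sample.int(length(ids), 1L)]
  structure(list(
    sequence_id = sid,
    stage = 0L,
    correct_trials_in_block = 0L,
    trial_index = 1L,
    trial_has_error = FALSE,
    pending_repeat = FALSE,
    repeat_count = 0L,
    max_repeat = as.integer(max_repeat)
  ), class = "task_state")
}

#' @export
print.task_state <- function(x, ...) {
  cat(sprintf(
    "<task_state> sequence S%d (%s), trial %d, stage %d, %d/8 error-free trials%s\n",
    x$sequence_id,
    task_sequences()$hemifield[task_sequences()$id == x$sequence_id],
    x$trial_index, x$stage, x$correct_trials_in_block,
    if (x$pending_repeat) ", repeat pending" else ""))
  invisible(x)
}

#' Actions available at the current state
#'
#' At every stage exactly two movement directions are available: the
#' left/right pair at the center for the first decision, the up/down pair on
#' the side reached by the first movement, and the left/right pair within
#' the hemifield reached by the second movement. Options outside the branch
#' implied by the prior correct movements are not available (e.g. for the
#' upper-hemifield sequences the lower-hemifield options cannot be chosen at
#' the later movement stages).
#'
#' @param state A \code{task_state}.
#' @return Integer vector of two direction ids.
#' @export
available_actions <- function(state) {
  stopifnot(inherits(state, "task_state"))
  mv <- seq_moves(state$sequence_id)
  switch(as.character(state$stage),
    "0" = c(1L, 2L),
    "1" = if (mv[1] == 1L) c(3L, 4L) else c(5L, 6L),
    "2" = if (mv[2] %in% c(3L, 5L)) c(7L, 8L) else c(9L, 10L),
    stop("invalid stage: ", state$stage))
}

#' Decision point of an executed action
#'
#' Maps a (stage, action) pair to one of the five decision points at which
#' rewards are delivered.
#'
#' @param stage Stage index 0-2.
#' @param action Direction id 1-10.
#' @return Integer index into \code{\link{decision_points}}.
#' @export
decision_point_of <- function(stage, action) {
  if (stage == 0L) return(1L)
  if (stage == 1L) return(if (action %in% c(3L, 5L)) 2L else 3L)
  if (action %in% c(7L, 8L)) 4L else 5L
}

#' Advance the task by one decision
#'
#' Applies an action to the current state. A correct action is rewarded and
#' advances the stage (the third correct action completes the trial); a
#' wrong action is unrewarded and the same stage is offered again (forced
#' repeat). A trial containing any error does not count towards the eight
#' error-free trials that terminate the block.
#'
#' @param state A \code{task_state}.
#' @param action A direction id; must be in \code{available_actions(state)}.
#' @return A list with elements \code{state} (the new \code{task_state}) and
#'   \code{outcome} (list with \code{reward} 0/1, \code{correct},
#'   \code{block_done}, \code{trial_done} and \code{decision_point}).
#' @export
task_step <- function(state, action) {
  avail <- available_actions(state)
  if (!action %in% avail) {
    stop(sprintf("action %d not available at stage %d (available: %s)",
                 action, state$stage, paste(avail, collapse = ", ")))
  }
  mv <- seq_moves(state$sequence_id)
  correct <- action == mv[state$stage + 1L]
  dp <- decision_point_of(state$stage, action)
  out <- list(reward = as.integer(correct), correct = correct,
              block_done = FALSE, trial_done = FALSE, decision_point = dp)
  if (correct) {
    state$pending_repeat <- FALSE
    state$repeat_count <- 0L
    if (state$stage == 2L) {
      out$trial_done <- TRUE
      if (!state$trial_has_error) {
        state$correct_trials_in_block <- state$correct_trials_in_block + 1L
      }
      if (state$correct_trials_in_block >= 8L) {
        out$block_done <- TRUE
      } else {
        state$stage <- 0L
        state$trial_index <- state$trial_index + 1L
        state$trial_has_error <- FALSE
      }
    } else {
      state$stage <- state$stage + 1L
    }
  } else {
    state$trial_has_error <- TRUE
    state$pending_repeat <- TRUE
    state$repeat_count <- state$repeat_count + 1L
    if (state$repeat_count > state$max_repeat) {
      stop("max_repeat exceeded: ", state$max_repeat,
           " consecutive errors at one decision")
    }
  }
  list(state = state, outcome = out)
}

#' Validate a trial log against the task rules
#'
#' Replays a behavior log decision-by-decision through the task state
#' machine and checks that every recorded stage, reward, correctness flag
#' and repeat flag is consistent with the rules.
#'
#' @param log A behavior log data.frame (see \code{\link{simulate_session}}
#'   for the schema).
#' @return Invisibly \code{TRUE}; throws an error on the first violation.
#' @export
validate_trial_log <- function(log) {
  stopifnot(is.data.frame(log), nrow(log) >= 1L)
  need <- c("block_id", "trial_index", "stage", "sequence_id", "action_id",
            "reward", "correct", "repeat_flag")
  if (!all(need %in% names(log))) {
    stop("log is missing columns: ", paste(setdiff(need, names(log)), collapse = ", "))
  }
  for (b in unique(log$block_id)) {
    lb <- log[log$block_id == b, , drop = FALSE]
    sid <- lb$sequence_id[1]
    if (!all(lb$sequence_id == sid)) stop("block ", b, ": sequence id changes mid-block")
    st <- new_block(max_repeat = .Machine$integer.max)
    st$sequence_id <- sid
    done <- FALSE
    for (i in seq_len(nrow(lb))) {
      if (done) stop("block ", b, ": decisions after block completion")
      if (lb$stage[i] != st$stage) stop("block ", b, " row ", i, ": stage mismatch")
      if (lb$trial_index[i] != st$trial_index) stop("block ", b, " row ", i, ": trial index mismatch")
      if (lb$repeat_flag[i] != st$pending_repeat) stop("block ", b, " row ", i, ": repeat flag mismatch")
      res <- task_step(st, lb$action_id[i])
      if (res$outcome$reward != lb$reward[i]) stop("block ", b, " row ", i, ": reward mismatch")
      if (res$outcome$correct != lb$correct[i]) stop("block ", b, " row ", i, ": correctness mismatch")
      st <- res$state
      done <- res$outcome$block_done
    }
    if (!done) stop("block ", b, ": log ends before block completion")
  }
  invisible(TRUE)
}

#' Write / read a behavior trial log as CSV
#'
#' @param log A behavior log data.frame.
#' @param path File path.
#' @return \code{read_trial_log} returns the log data.frame.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  log <- utils::read.csv(path)
  log$correct <- as.logical(log$correct)
  log$repeat_flag <- as.logical(log$repeat_flag)
  log
}
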