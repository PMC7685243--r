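## Signal coding: behavior logs + Q-derived value traces -> time-resolved
## input and target tensors for the two networks.
##
## A block with D decisions is coded as D+1 segments. Segment d (d >= 1)
## replays decision d into the striatal network (action pulse on its
## direction channel, reward pulse on its decision-point channel at the end
## of the action pulse) while the prefrontal target is the action pulse of
## decision d+1 -- the prefrontal network always produces the *next* action.
## Segment 0 carries the white-noise action input that opens a block.
## Each segment is [fixation gap | action pulse | reward pulse]; the
## instruction channels mark Fixate during the gap and Move+Hold during the
## action pulse, on the channel(s) of the upcoming decision point.

#' Coding configuration
#'
#' Pulse geometry for the tensor coding. One time-step is \code{dt} ms of
#' network time (default 1 ms, so with the 10 ms neural time constant the
#' Euler factor is 0.1). The reward pulse is always 2/10 of the action
#' pulse. The fixation gap doubles as the fixation period used by the
#' fixed-point verification (10 steps by default).
#'
#' @param action_pulse_len Length of the action pulse in steps.
#' @param gap Fixation gap before the action pulse, in steps.
#' @param dt Milliseconds per step.
#' @param noise_sd SD of the white-noise action input that opens a block.
#' @param value_hold \code{"zoh"} (zero-order hold of value targets between
#'   decisions, default) or \code{"linear"} for linear interpolation across
#'   the pre-reward epoch.
#' @return An object of class \code{coding_config}.
#' @export
coding_config <- function(action_pulse_len = 50L, gap = 10L, dt = 1,
                          noise_sd = 0.01, value_hold = c("zoh", "linear")) {
  value_hold <- match.arg(value_hold)
  reward_pulse_len <- max(1L, as.integer(round(0.2 * action_pulse_len)))
  stopifnot(action_pulse_len >= 1L, gap >= 1L, dt > 0)
  structure(list(action_pulse_len = as.integer(action_pulse_len),
                 reward_pulse_len = reward_pulse_len,
                 gap = as.integer(gap), dt = dt, noise_sd = noise_sd,
                 value_hold = value_hold,
                 seg_len = as.integer(gap + action_pulse_len + reward_pulse_len)),
            class = "coding_config")
}

## instruction channels of a decision, given its stage and the block's
## sequence: Fixate channel 2j-1, Move+Hold channel 2j for decision point j.
## Stage 1 shows both the upwards and downwards targets (the choice is
## between them); stage 2 shows the hemifield actually reached.
instruction_points <- function(stage, hemifield) {
  switch(as.character(stage),
    "0" = 1L,
    "1" = c(2L, 3L),
    "2" = if (hemifield == "upper") 4L else 5L,
    stop("invalid stage: ", stage))
}

#' Encode one block as network input/target tensors
#'
#' @param log_block Rows of a behavior log belonging to one block.
#' @param value_traces List with matrices \code{pre} and \code{post}
#'   (as returned by \code{\link{generate_value_traces}}), sliced to the
#'   same rows as \code{log_block}.
#' @param cfg A \code{\link{coding_config}}.
#' @return An object of class \code{trial_tensors}: matrices \code{u_s}
#'   (T x 15 striatal input: 10 action + 5 reward channels), \code{u_ins}
#'   (T x 10 prefrontal instruction input), \code{y_v} (T x 10 striatal
#'   value target), \code{y_a} (T x 11 prefrontal target: 10 next-action
#'   channels + hemifield unit), and a \code{segments} table mapping
#'   segments to the decisions they replay and decode.
#' @export
encode_block <- function(log_block, value_traces, cfg = coding_config()) {
  stopifnot(inherits(cfg, "coding_config"), is.data.frame(log_block))
  D <- nrow(log_block)
  L <- cfg$seg_len
  if (D == 0L) {
    return(structure(list(
      u_s = matrix(0, 0, 15), u_ins = matrix(0, 0, 10),
      y_v = matrix(0, 0, 10), y_a = matrix(0, 0, 11),
      segments = data.frame(), cfg = cfg, sequence_id = NA_integer_),
      class = "trial_tensors"))
  }
  if (any(log_block$action_id < 1L | log_block$action_id > 10L)) {
    stop("action id outside the 10-direction vocabulary")
  }
  stopifnot(nrow(value_traces$pre) == D, nrow(value_traces$post) == D)
  sid <- log_block$sequence_id[1]
  hemi <- task_sequences()$hemifield[task_sequences()$id == sid]
  uvis <- if (hemi == "upper") 1 else -1

  Tn <- (D + 1L) * L
  u_s <- matrix(0, Tn, 15)
  u_ins <- matrix(0, Tn, 10)
  y_v <- matrix(0, Tn, 10)
  y_a <- matrix(0, Tn, 11)
  y_a[, 11] <- uvis

  fix_rows <- function(d) (d * L) + seq_len(cfg$gap)
  act_rows <- function(d) (d * L) + cfg$gap + seq_len(cfg$action_pulse_len)
  rew_rows <- function(d) (d * L) + cfg$gap + cfg$action_pulse_len +
    seq_len(cfg$reward_pulse_len)

  segments <- data.frame(
    segment = 0:D,
    replays_decision = c(NA_integer_, seq_len(D)),
    decodes_decision = c(seq_len(D), NA_integer_),
    act_start = (0:D) * L + cfg$gap + 1L,
    act_end = (0:D) * L + cfg$gap + cfg$action_pulse_len)

  ## segment 0: white-noise action input, value target = initial values
  u_s[act_rows(0L), 1:10] <- stats::rnorm(cfg$action_pulse_len * 10L,
                                          0, cfg$noise_sd)
  y_v[seq_len(L), ] <- matrix(value_traces$pre[1L, ], L, 10, byrow = TRUE)

  for (d in seq_len(D)) {
    act <- log_block$action_id[d]
    stage <- log_block$stage[d]
    ## striatal input: replay decision d
    u_s[act_rows(d), act] <- 1
    if (log_block$reward[d] == 1L) {
      dp <- decision_point_of(stage, act)
      u_s[rew_rows(d), 10L + dp] <- 1
    }
    ## value target: pre-decision values until reward onset, post after
    qpre <- value_traces$pre[d, ]
    qpost <- value_traces$post[d, ]
    pre_rows <- c(fix_rows(d), act_rows(d))
    if (cfg$value_hold == "zoh") {
      y_v[pre_rows, ] <- matrix(qpre, length(pre_rows), 10, byrow = TRUE)
    } else {
      w <- seq(0, 1, length.out = length(pre_rows))
      y_v[pre_rows, ] <- outer(1 - w, qpre) + outer(w, qpost)
    }
    y_v[rew_rows(d), ] <- matrix(qpost, cfg$reward_pulse_len, 10, byrow = TRUE)
  }
  ## prefrontal targets + instructions: segment d codes decision d+1
  for (d in 0:(D - 1L)) {
    nxt <- d + 1L
    act <- log_block$action_id[nxt]
    stage <- log_block$stage[nxt]
    y_a[act_rows(d), act] <- 1
    pts <- instruction_points(stage, hemi)
    u_ins[fix_rows(d), 2L * pts - 1L] <- 1
    u_ins[act_rows(d), 2L * pts] <- 1
  }
  structure(list(u_s = u_s, u_ins = u_ins, y_v = y_v, y_a = y_a,
                 segments = segments, cfg = cfg, sequence_id = sid,
                 hemifield = hemi, log = log_block),
            class = "trial_tensors")
}

#' @export
print.trial_tensors <- function(x, ...) {
  cat(sprintf("<trial_tensors> S%s, %d decisions, %d time steps (%d-step segments)\n",
              x$sequence_id, nrow(x$log), nrow(x$u_s), x$cfg$seg_len))
  invisible(x)
}

#' Build a train/test dataset of encoded blocks
#'
#' Encodes every block of a behavior log (with its Q-derived value traces),
#' then splits at block granularity into a training and a held-out test
#' set. Optional augmentation blocks (e.g. extra synthetic sessions) are
#' encoded and appended to the training set only.
#'
#' @param log A behavior log data.frame.
#' @param params \code{\link{q_params}} used to derive the value traces.
#' @param cfg A \code{\link{coding_config}}.
#' @param test_blocks Number of blocks held out as the test set (default 25).
#' @param augment Optional second behavior log used for training only.
#' @return An object of class \code{rnn_dataset}: lists \code{train} and
#'   \code{test} of \code{\link{encode_block}} tensors, plus the block-id
#'   split.
#' @export
build_dataset <- function(log, params = q_params(), cfg = coding_config(),
                          test_blocks = 25L, augment = NULL) {
  ids <- unique(log$block_id)
  if (length(ids) < test_blocks + 1L) {
    stop("need more than ", test_blocks, " blocks; got ", length(ids))
  }
  traces <- generate_value_traces(log, params)
  test_ids <- sort(sample(ids, test_blocks))
  train_ids <- setdiff(ids, test_ids)
  enc <- function(b) {
    rows <- which(log$block_id == b)
    encode_block(log[rows, , drop = FALSE],
                 list(pre = traces$pre[rows, , drop = FALSE],
                      post = traces$post[rows, , drop = FALSE]), cfg)
  }
  train <- lapply(train_ids, enc)
  test <- lapply(test_ids, enc)
  if (!is.null(augment)) {
    atr <- generate_value_traces(augment, params)
    for (b in unique(augment$block_id)) {
      rows <- which(augment$block_id == b)
      train[[length(train) + 1L]] <- encode_block(
        augment[rows, , drop = FALSE],
        list(pre = atr$pre[rows, , drop = FALSE],
             post = atr$post[rows, , drop = FALSE]), cfg)
    }
  }
  structure(list(train = train, test = test, train_ids = train_ids,
                 test_ids = test_ids, cfg = cfg, params = params),
            class = "rnn_dataset")
}

#' @export
print.rnn_dataset <- function(x, ...) {
  cat(sprintf("<rnn_dataset> %d training blocks, %d test blocks\n",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Sample a training batch of blocks
#'
#' Draws \code{k} blocks uniformly with replacement from across the entire
#' training set (the sampling unit of one gradient step).
#'
#' @param dataset An \code{rnn_dataset} (or a plain list of tensors).
#' @param k Batch size (default 10).
#' @return List of \code{k} \code{trial_tensors}.
#' @export
sample_batch <- function(dataset, k = 10L) {
  train <- if (inherits(dataset, "rnn_dataset")) dataset$train else dataset
  if (length(train) == 0L) stop("empty training set")
  train[sample.int(length(train), k, replace = TRUE)]
}
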