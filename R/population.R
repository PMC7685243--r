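## Assembling trial-averaged population tensors (units x sequences x
## certainty x time) from closed-loop runs, for the dPCA / distance /
## potential-surface analyses. A trial's time course is the concatenation
## of the three segments replaying the first attempt at each movement
## stage, so every trial contributes the same number of time steps
## regardless of how many forced repeats it contained.

#' Trial-averaged population tensor from a closed-loop run
#'
#' Averages the recorded unit activity of an \code{\link{run_autonomous}}
#' run (with \code{record_states = TRUE}) over trials, within cells of
#' sequence x certainty bin. Certainty bins come from
#' \code{\link{assign_certainty}} on the run's own behavior log. Every
#' (sequence, certainty) cell must be visited at least \code{min_trials}
#' times; simulate more blocks if the tensor comes back unbalanced.
#'
#' @param run An \code{autonomous_run} with recorded states.
#' @param area \code{"prefrontal"} or \code{"striatal"}.
#' @param activity \code{"rate"} (tanh of currents, default) or
#'   \code{"current"}.
#' @param certainty Optional precomputed certainty table; defaults to
#'   \code{assign_certainty(run$log)}.
#' @param min_trials Minimum trials per cell.
#' @return A list of class \code{population_data}: \code{X} (units x 8 x
#'   n_levels x T tensor), the mean value-readout tensor \code{u_v}
#'   (10 x 8 x n_levels x T), cell counts, and the certainty labels.
#' @export
population_tensor <- function(run, area = c("prefrontal", "striatal"),
                              activity = c("rate", "current"),
                              certainty = NULL, min_trials = 1L) {
  stopifnot(inherits(run, "autonomous_run"))
  area <- match.arg(area)
  activity <- match.arg(activity)
  if (!run$record_states) stop("run_autonomous() must record states")
  if (is.null(certainty)) certainty <- assign_certainty(run$log)
  levels_c <- levels(certainty$certainty)
  n_lev <- length(levels_c)
  L <- run$cfg$seg_len
  Tn <- 3L * L
  xfield <- if (area == "prefrontal") "x_p" else "x_s"
  n_units <- ncol(run$blocks[[1]][[xfield]])

  sum_x <- array(0, c(n_units, 8L, n_lev, Tn))
  sum_uv <- array(0, c(10L, 8L, n_lev, Tn))
  counts <- matrix(0L, 8L, n_lev)

  log <- run$log
  for (b in seq_along(run$blocks)) {
    blk <- run$blocks[[b]]
    sid <- blk$sequence_id
    lb_rows <- which(log$block_id == b)
    lb <- log[lb_rows, , drop = FALSE]
    seg <- blk$segments
    for (tr in unique(lb$trial_index)) {
      ## first-attempt decisions of the three stages of this trial
      firsts <- vapply(0:2, function(stg) {
        i <- which(lb$trial_index == tr & lb$stage == stg & !lb$repeat_flag)
        if (length(i)) i[1] else NA_integer_
      }, integer(1))
      if (anyNA(firsts)) next
      segs <- match(firsts, seg$decodes_decision)
      if (anyNA(segs)) next
      cert <- certainty$certainty[certainty$block_id == b &
                                    certainty$trial_index == tr]
      ci <- match(as.character(cert), levels_c)
      rows <- unlist(lapply(segs, function(si) (si - 1L) * L + seq_len(L)))
      xx <- t(blk[[xfield]][rows, , drop = FALSE])
      if (activity == "rate") xx <- tanh(xx)
      sum_x[, sid, ci, ] <- sum_x[, sid, ci, ] + xx
      sum_uv[, sid, ci, ] <- sum_uv[, sid, ci, ] + t(blk$u_v[rows, , drop = FALSE])
      counts[sid, ci] <- counts[sid, ci] + 1L
    }
  }
  if (any(counts < min_trials)) {
    bad <- which(counts < min_trials, arr.ind = TRUE)
    stop("unbalanced population tensor: ", nrow(bad),
         " (sequence, certainty) cells have fewer than ", min_trials,
         " trials; simulate more blocks")
  }
  X <- sum_x
  UV <- sum_uv
  for (s_i in 1:8) for (c_i in seq_len(n_lev)) {
    X[, s_i, c_i, ] <- X[, s_i, c_i, ] / counts[s_i, c_i]
    UV[, s_i, c_i, ] <- UV[, s_i, c_i, ] / counts[s_i, c_i]
  }
  structure(list(X = X, u_v = UV, counts = counts,
                 certainty_levels = levels_c, area = area,
                 activity = activity, cfg = run$cfg,
                 hemifield = task_sequences()$hemifield),
            class = "population_data")
}

#' @export
print.population_data <- function(x, ...) {
  cat(sprintf("<population_data> %s %s tensor: %d units x %d seq x %d certainty x %d steps\n",
              x$area, x$activity, dim(x$X)[1], dim(x$X)[2], dim(x$X)[3],
              dim(x$X)[4]))
  cat("  trials per cell: min", min(x$counts), "median",
      stats::median(x$counts), "\n")
  invisible(x)
}

#' Project a population tensor into a reduced dPC space
#'
#' Projects every (sequence, certainty) trajectory of a population tensor
#' onto the leading sequence-subspace decoders, producing a d x sequences x
#' certainty x time array. Distance analyses on model data are typically
#' run in a 10-dimensional sequence dPC space.
#'
#' @param pop A \code{population_data} object (or a bare 4-d tensor).
#' @param model A \code{\link{fit_dpca}} model fitted to the same tensor.
#' @param phi Marginalization subspace.
#' @param d Latent dimensionality.
#' @param sigma Gaussian smoothing (time bins).
#' @return A d x sequences x certainty x time array.
#' @export
project_tensor <- function(pop, model, phi = "s", d = 10L, sigma = 0) {
  X <- if (inherits(pop, "population_data")) pop$X else pop
  S <- dim(X)[2]; C <- dim(X)[3]; Tn <- dim(X)[4]
  D <- model$D[[phi]]
  d <- min(d, nrow(D))
  out <- array(0, c(d, S, C, Tn))
  for (s_i in seq_len(S)) for (c_i in seq_len(C)) {
    out[, s_i, c_i, ] <- t(dpca_project(X[, s_i, c_i, ], model, phi = phi,
                                        d = d, sigma = sigma))
  }
  out
}
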