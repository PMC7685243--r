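## Temporal-difference (Q-learning) model of trial-by-trial choice:
## one action value per movement direction, availability masking supplies
## the state structure, softmax choice, per-decision value decay.

#' Q-learning parameters
#'
#' Container for the four parameters of the behavioral value model: the
#' learning rate \code{alpha}, the discount factor \code{gamma}, the softmax
#' inverse temperature \code{beta}, and the per-decision multiplicative
#' value decay \code{tau_q}. Defaults are the values fitted to monkey
#' training-session choice data (alpha = 0.8100, gamma = 0.2010,
#' beta = 3.050) with the decay fixed at tau_q = 0.95.
#'
#' @param alpha Learning rate in (0, 1].
#' @param gamma Discount factor in [0, 1).
#' @param beta Inverse temperature, > 0.
#' @param tau_q Per-decision decay in (0, 1].
#' @return An object of class \code{q_params}.
#' @export
q_params <- function(alpha = 0.8100, gamma = 0.2010, beta = 3.050,
                     tau_q = 0.95) {
  stopifnot(is.finite(alpha), alpha > 0, alpha <= 1,
            is.finite(gamma), gamma >= 0, gamma < 1,
            is.finite(beta), beta > 0,
            is.finite(tau_q), tau_q > 0, tau_q <= 1)
  structure(list(alpha = alpha, gamma = gamma, beta = beta, tau_q = tau_q),
            class = "q_params")
}

#' @export
print.q_params <- function(x, ...) {
  cat(sprintf("<q_params> alpha=%.4f gamma=%.4f beta=%.3f tau_q=%.3f\n",
              x$alpha, x$gamma, x$beta, x$tau_q))
  invisible(x)
}

#' Temporal-difference update of one action value
#'
#' Applies the one-step TD update
#' \eqn{Q(a) \leftarrow Q(a) + \alpha [r + \gamma \max_{a'} Q(a') - Q(a)]}
#' where the maximum runs over the actions available in the successor state
#' (zero for the terminal transition after the third correct decision of a
#' trial). Only the entry of the taken action changes.
#'
#' @param q Numeric vector of 10 action values.
#' @param action Direction id of the taken action.
#' @param reward Reward received (0 or 1).
#' @param next_available Integer vector of direction ids available in the
#'   successor state, or \code{NULL}/empty for a terminal transition.
#' @param params A \code{\link{q_params}} object.
#' @return The updated 10-vector.
#' @export
q_update <- function(q, action, reward, next_available, params) {
  stopifnot(inherits(params, "q_params"), length(q) == 10L,
            action >= 1L, action <= 10L)
  nxt <- if (is.null(next_available) || length(next_available) == 0L) 0
         else max(q[next_available])
  q[action] <- q[action] +
    params$alpha * (reward + params$gamma * nxt - q[action])
  q
}

#' Multiplicative value decay
#'
#' Every action value is multiplied by \code{tau_q}; applied once per
#' decision, after the TD update.
#'
#' @inheritParams q_update
#' @return The decayed 10-vector.
#' @export
q_decay <- function(q, params) {
  stopifnot(inherits(params, "q_params"))
  q * params$tau_q
}

#' Softmax choice probabilities over available actions
#'
#' @param q Numeric vector of 10 action values.
#' @param available Integer vector of available direction ids (non-empty).
#' @param params A \code{\link{q_params}} object.
#' @return Named probability vector over \code{available}, summing to 1.
#' @export
choice_probs <- function(q, available, params) {
  stopifnot(inherits(params, "q_params"))
  if (length(available) == 0L) stop("empty set of available actions")
  z <- params$beta * q[available]
  z <- z - max(z)            # shift invariance / overflow guard
  p <- exp(z)
  p <- p / sum(p)
  names(p) <- task_directions()[available]
  p
}

## Replay a trial log once through the task rules and flatten it into
## plain vectors (action, reward, available pair, successor pair, terminal
## flag) so that likelihood evaluation and value-trace generation are
## simple loops with no task-environment calls inside. Unlike
## validate_trial_log(), partial blocks (e.g. single encoded trials) are
## accepted; consistency of stages, rewards and repeats is still enforced
## by the replay itself.
compile_log <- function(log) {
  stopifnot(is.data.frame(log), nrow(log) >= 1L)
  n <- nrow(log)
  avail <- matrix(0L, n, 2L)
  nxt <- matrix(0L, n, 2L)
  terminal <- logical(n)
  i <- 0L
  for (b in unique(log$block_id)) {
    lb <- log[log$block_id == b, , drop = FALSE]
    st <- new_block(max_repeat = .Machine$integer.max)
    st$sequence_id <- lb$sequence_id[1]
    done <- FALSE
    for (k in seq_len(nrow(lb))) {
      i <- i + 1L
      if (done) stop("block ", b, ": decisions after block completion")
      if (lb$stage[k] != st$stage) stop("block ", b, " row ", k, ": stage mismatch")
      avail[i, ] <- available_actions(st)
      res <- task_step(st, lb$action_id[k])
      if (res$outcome$reward != lb$reward[k]) {
        stop("block ", b, " row ", k, ": reward inconsistent with task rules")
      }
      st <- res$state
      done <- res$outcome$block_done
      if (res$outcome$trial_done) {
        terminal[i] <- TRUE
      } else {
        nxt[i, ] <- available_actions(st)
      }
    }
  }
  list(n = n, action = log$action_id, reward = log$reward,
       avail = avail, nxt = nxt, terminal = terminal,
       block_id = log$block_id, trial_index = log$trial_index,
       stage = log$stage, repeat_flag = log$repeat_flag)
}

#' Replay a behavior log through the value model
#'
#' Replays a trial log decision-by-decision through the TD update and the
#' per-decision decay, recording the full 10-vector of action values before
#' and after each decision. Values of rewarded actions rise after the
#' reward; values of unrewarded (wrong) actions fall and then decay towards
#' zero.
#'
#' @param log A behavior log data.frame.
#' @param params A \code{\link{q_params}} object.
#' @param q0 Initial value vector (default all zeros).
#' @return A list with matrices \code{pre} and \code{post}
#'   (decisions x 10): values in force when the decision was made, and
#'   values after the update and decay triggered by its outcome.
#' @export
generate_value_traces <- function(log, params, q0 = rep(0, 10)) {
  stopifnot(inherits(params, "q_params"), length(q0) == 10L)
  if (is.null(log) || nrow(log) == 0L) {
    return(list(pre = matrix(0, 0, 10), post = matrix(0, 0, 10)))
  }
  cl <- compile_log(log)
  pre <- post <- matrix(0, cl$n, 10L)
  q <- q0
  for (i in seq_len(cl$n)) {
    pre[i, ] <- q
    nxt <- if (cl$terminal[i]) integer(0) else cl$nxt[i, ]
    q <- q_update(q, cl$action[i], cl$reward[i], nxt, params)
    q <- q_decay(q, params)
    post[i, ] <- q
  }
  list(pre = pre, post = post)
}

## Negative log-likelihood of the observed choices under the model, on a
## compiled log (C++ inner loop; this is the objective of the fit).
qlearn_nll <- function(theta, cl) {
  qlearn_nll_cpp(as.integer(cl$action), as.integer(cl$reward),
                 cl$avail, cl$nxt, cl$terminal,
                 theta[1], theta[2], theta[3], theta[4])
}

#' Fit Q-learning parameters to a choice log by maximum likelihood
#'
#' Minimizes the negative log-likelihood of the observed choices under the
#' softmax Q-learning model using derivative-free Nelder-Mead simplex
#' search (the R analogue of Matlab's \code{fminsearch}) in an unconstrained
#' reparameterization, with random restarts. The decay parameter is held
#' fixed by default, as in the original behavioral fit (tau_q = 0.95).
#'
#' @param log A behavior log with at least 50 decisions.
#' @param init Initial \code{\link{q_params}}.
#' @param fixed_tau If \code{TRUE} (default) \code{tau_q} is not fitted.
#' @param n_restarts Number of random restarts around \code{init}.
#' @return An object of class \code{qfit} with components \code{params}
#'   (fitted \code{q_params}), \code{nll}, \code{convergence}, \code{n_obs}
#'   and the per-restart table \code{restarts}.
#' @export
fit_qlearning <- function(log, init = q_params(), fixed_tau = TRUE,
                          n_restarts = 10L) {
  if (is.null(log) || nrow(log) == 0L) stop("empty behavior log")
  if (nrow(log) < 50L) stop("need at least 50 decisions to fit; got ", nrow(log))
  stopifnot(inherits(init, "q_params"))
  cl <- compile_log(log)

  ## unconstrained scale: logit(alpha), logit(gamma), log(beta), logit(tau)
  to_free <- function(p) c(stats::qlogis(p$alpha), stats::qlogis(p$gamma),
                           log(p$beta), stats::qlogis(p$tau_q))
  from_free <- function(v, tau_fixed) {
    tau <- if (fixed_tau) tau_fixed else stats::plogis(v[4])
    c(stats::plogis(v[1]), stats::plogis(v[2]), exp(v[3]), tau)
  }
  npar <- if (fixed_tau) 3L else 4L
  v_full <- to_free(init)
  obj <- function(v) {
    w <- v_full
    w[seq_len(npar)] <- v
    th <- from_free(w, init$tau_q)
    val <- qlearn_nll(th, cl)
    if (!is.finite(val)) stop("non-finite likelihood at alpha=", th[1],
                              " gamma=", th[2], " beta=", th[3])
    val
  }
  v0 <- v_full[seq_len(npar)]
  starts <- rbind(v0, matrix(rep(v0, n_restarts), nrow = n_restarts, byrow = TRUE) +
                        matrix(stats::rnorm(n_restarts * npar, 0, 0.8), n_restarts))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    op <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-9))
    list(par = op$par, value = op$value, convergence = op$convergence)
  })
  nlls <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(nlls)]]
  w <- v_full
  w[seq_len(npar)] <- best$par
  th <- from_free(w, init$tau_q)
  res <- structure(list(
    params = q_params(alpha = th[1], gamma = th[2], beta = th[3], tau_q = th[4]),
    nll = best$value,
    convergence = best$convergence,
    converged = best$convergence == 0L,
    n_obs = cl$n,
    fixed_tau = fixed_tau,
    restarts = data.frame(restart = seq_along(nlls) - 1L, nll = nlls)
  ), class = "qfit")
  if (!res$converged) warning("Nelder-Mead did not report convergence")
  res
}

#' @export
print.qfit <- function(x, ...) {
  cat(sprintf(
    "Q-learning fit (%d decisions): alpha=%.4f gamma=%.4f beta=%.3f tau_q=%.3f%s\n",
    x$n_obs, x$params$alpha, x$params$gamma, x$params$beta, x$params$tau_q,
    if (x$fixed_tau) " (fixed)" else ""))
  cat(sprintf("  negative log-likelihood: %.3f (%d restarts)\n",
              x$nll, nrow(x$restarts) - 1L))
  invisible(x)
}

#' @export
coef.qfit <- function(object, ...) {
  unlist(object$params)
}

#' @export
logLik.qfit <- function(object, ...) {
  structure(-object$nll, df = if (object$fixed_tau) 3L else 4L,
            nobs = object$n_obs, class = "logLik")
}

#' Negative log-likelihood of a log at given parameters
#'
#' Utility for likelihood surfaces and fit diagnostics: evaluates the same
#' objective that \code{\link{fit_qlearning}} minimizes.
#'
#' @inheritParams fit_qlearning
#' @param params A \code{\link{q_params}} object.
#' @return Scalar negative log-likelihood.
#' @export
qlearning_nll <- function(log, params) {
  stopifnot(inherits(params, "q_params"))
  cl <- compile_log(log)
  qlearn_nll(c(params$alpha, params$gamma, params$beta, params$tau_q), cl)
}
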