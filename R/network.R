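## The coupled striatal/prefrontal rate networks: initialization, Euler
## dynamics (C++ core), rollouts, readouts, eigenspectrum diagnostics.

#' Initialize the corticostriatal network system
#'
#' Two recurrent tanh rate networks coupled through their readouts: a
#' striatal network (15-D input: 10 action + 5 reward channels; 10-D value
#' readout) and a prefrontal network (20-D input: the 10-D striatal value
#' readout plus 10 instruction channels; 11-D readout: 10 action channels
#' plus a hemifield unit). Recurrent weights are drawn i.i.d. standard
#' normal and scaled by \code{g/sqrt(N)}; input and readout weights are
#' scaled by the reciprocal square root of their true fan-in. Readouts are
#' taken from the synaptic currents, not the rates. Dynamics are integrated
#' by explicit Euler with step \code{dt} (the Euler factor is
#' \code{dt/tau}); each unit receives independent white noise of SD
#' \code{noise_sd} inside the update.
#'
#' The full-scale system has 1300 striatal and 1000 prefrontal units; a
#' 5-fold reduced system (260/200) reproduces all qualitative results at a
#' fraction of the cost and is what the examples and tests use.
#'
#' @param n_s,n_p Numbers of striatal and prefrontal units.
#' @param g Recurrent gain.
#' @param tau Neural time constant in ms.
#' @param dt Integration step in ms (must not exceed \code{tau}).
#' @param noise_sd SD of the per-unit white-noise input.
#' @return An object of class \code{corticostriatal_net} holding the six
#'   weight matrices and the dynamics constants.
#' @export
init_network <- function(n_s = 1300L, n_p = 1000L, g = 1.0, tau = 10,
                         dt = 1, noise_sd = 0.01) {
  stopifnot(n_s >= 2L, n_p >= 2L, dt <= tau, dt > 0)
  rmat <- function(nr, nc, scale) {
    matrix(stats::rnorm(nr * nc), nr, nc) * scale
  }
  structure(list(
    W_rr_s = rmat(n_s, n_s, g / sqrt(n_s)),
    W_ir_s = rmat(n_s, 15L, 1 / sqrt(15)),
    W_ro_s = rmat(10L, n_s, 1 / sqrt(n_s)),
    W_rr_p = rmat(n_p, n_p, g / sqrt(n_p)),
    W_ir_p = rmat(n_p, 20L, 1 / sqrt(20)),
    W_ro_p = rmat(11L, n_p, 1 / sqrt(n_p)),
    n_s = as.integer(n_s), n_p = as.integer(n_p),
    g = g, tau = tau, dt = dt, noise_sd = noise_sd,
    trained = FALSE, loss_history = NULL
  ), class = "corticostriatal_net")
}

#' @export
print.corticostriatal_net <- function(x, ...) {
  cat(sprintf(
    "<corticostriatal_net> striatal %d units, prefrontal %d units (g=%.2f, tau=%g ms, dt=%g ms, noise sd=%g)\n",
    x$n_s, x$n_p, x$g, x$tau, x$dt, x$noise_sd))
  if (x$trained) {
    lh <- x$loss_history
    cat(sprintf("  trained: %d iterations, loss %.4g -> %.4g\n",
                nrow(lh), lh$loss[1], lh$loss[nrow(lh)]))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

net_noise <- function(net, Tn, noise) {
  if (!noise || net$noise_sd <= 0 || Tn == 0L) {
    list(s = matrix(0, 0, 0), p = matrix(0, 0, 0))
  } else {
    list(s = matrix(stats::rnorm(Tn * net$n_s, 0, net$noise_sd), Tn),
         p = matrix(stats::rnorm(Tn * net$n_p, 0, net$noise_sd), Tn))
  }
}

#' Roll the network system over an input tensor
#'
#' Integrates both networks over the full length of a block's input
#' tensors, returning the value and action readout time series (and,
#' optionally, the full synaptic-current traces for population analysis).
#'
#' @param net A \code{corticostriatal_net}.
#' @param tensors A \code{\link{trial_tensors}} object, or any list with
#'   matrices \code{u_s} (T x 15) and \code{u_ins} (T x 10).
#' @param x0_s,x0_p Initial synaptic currents (default zero).
#' @param noise Logical: inject white-noise input? (Draws from R's global
#'   RNG, so rollouts are reproducible under \code{set.seed}.)
#' @param record_states Logical: return the T x N current matrices?
#' @return List with \code{u_v} (T x 10), \code{u_a} (T x 11), final
#'   currents \code{x_end_s}/\code{x_end_p}, and (if requested) \code{x_s},
#'   \code{x_p}.
#' @export
net_rollout <- function(net, tensors, x0_s = NULL, x0_p = NULL,
                        noise = TRUE, record_states = FALSE) {
  stopifnot(inherits(net, "corticostriatal_net"))
  u_s <- tensors$u_s; u_ins <- tensors$u_ins
  stopifnot(ncol(u_s) == 15L, ncol(u_ins) == 10L,
            nrow(u_s) == nrow(u_ins))
  if (nrow(u_s) == 0L) {
    return(list(u_v = matrix(0, 0, 10), u_a = matrix(0, 0, 11),
                x_end_s = x0_s %||% rep(0, net$n_s),
                x_end_p = x0_p %||% rep(0, net$n_p)))
  }
  if (is.null(x0_s)) x0_s <- rep(0, net$n_s)
  if (is.null(x0_p)) x0_p <- rep(0, net$n_p)
  eta <- net_noise(net, nrow(u_s), noise)
  rnn_rollout_cpp(net$W_rr_s, net$W_ir_s, net$W_ro_s,
                  net$W_rr_p, net$W_ir_p, net$W_ro_p,
                  u_s, u_ins, x0_s, x0_p, net$dt / net$tau,
                  eta$s, eta$p, record_states)
}

#' Single Euler step of the network system
#'
#' One integration step; mainly useful for fixed-point and potential
#' surface work, and for tests against hand-computed updates.
#'
#' @inheritParams net_rollout
#' @param x_s,x_p Current synaptic-current vectors.
#' @param u_s 15-vector of striatal input.
#' @param u_ins 10-vector of prefrontal instruction input.
#' @return List with new \code{x_s}, \code{x_p} and readouts \code{u_v},
#'   \code{u_a}.
#' @export
net_step <- function(net, x_s, x_p, u_s, u_ins, noise = FALSE) {
  out <- net_rollout(net,
                     list(u_s = matrix(u_s, 1L), u_ins = matrix(u_ins, 1L)),
                     x0_s = x_s, x0_p = x_p, noise = noise)
  list(x_s = drop(out$x_end_s), x_p = drop(out$x_end_p),
       u_v = drop(out$u_v), u_a = drop(out$u_a))
}

#' Eigenvalue spectrum of a weight matrix
#'
#' Complex eigenvalues sorted by decreasing modulus. For an i.i.d. matrix
#' scaled by \code{g/sqrt(N)} the spectrum fills a disc of radius ~g
#' (circular law); training reshapes it, typically stretching a few modes
#' beyond the disc.
#'
#' @param W A square matrix, or a \code{corticostriatal_net} (in which case
#'   \code{which} selects the recurrent matrix).
#' @param which \code{"striatal"} or \code{"prefrontal"}.
#' @return Complex vector of eigenvalues, decreasing in modulus.
#' @export
eig_spectrum <- function(W, which = c("striatal", "prefrontal")) {
  if (inherits(W, "corticostriatal_net")) {
    which <- match.arg(which)
    W <- if (which == "striatal") W$W_rr_s else W$W_rr_p
  }
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  ev <- eigen(W, only.values = TRUE)$values
  ev <- as.complex(ev)
  ev[order(Mod(ev), decreasing = TRUE)]
}

#' Plot an eigenvalue spectrum in the complex plane
#'
#' @param ev Complex eigenvalues (from \code{\link{eig_spectrum}}).
#' @param ... Passed to \code{plot}.
#' @export
plot_spectrum <- function(ev, ...) {
  graphics::plot(Re(ev), Im(ev), asp = 1, pch = 16, cex = 0.5,
                 xlab = "Re", ylab = "Im", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), lty = 3)
  invisible(ev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
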