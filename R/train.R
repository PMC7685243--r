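## Joint supervised training of the two networks: squared-error loss with
## double weight on the striatal (value) term, BPTT gradients from the C++
## core, Adam (or plain SGD) with a geometrically decaying learning rate.

#' Training configuration
#'
#' The reference schedule is an initial learning rate of 0.001 for 10 outer
#' steps of 1000 iterations each, the rate multiplied by 2/3 at every outer
#' step, batches of 10 blocks drawn with replacement per iteration, and
#' double weight on the striatal loss term. Reduced settings (fewer outer
#' steps/iterations) are used for the scaled-down system.
#'
#' @param lr0 Initial learning rate.
#' @param n_outer Number of outer steps.
#' @param iters_per_outer Gradient iterations per outer step.
#' @param lr_decay Multiplicative learning-rate decay per outer step; the
#'   learning rate at (0-based) outer step k is \code{lr0 * lr_decay^k}.
#' @param batch_k Blocks per batch.
#' @param striatal_weight Weight of the striatal loss term.
#' @param optimizer \code{"adam"} (default) or \code{"sgd"}.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(lr0 = 0.001, n_outer = 10L, iters_per_outer = 1000L,
                         lr_decay = 2 / 3, batch_k = 10L,
                         striatal_weight = 2, optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr0 > 0, n_outer >= 1L, iters_per_outer >= 1L,
            lr_decay > 0, lr_decay <= 1, batch_k >= 1L, striatal_weight >= 0)
  structure(list(lr0 = lr0, n_outer = as.integer(n_outer),
                 iters_per_outer = as.integer(iters_per_outer),
                 lr_decay = lr_decay, batch_k = as.integer(batch_k),
                 striatal_weight = striatal_weight, optimizer = optimizer),
            class = "train_config")
}

#' Joint squared-error loss
#'
#' \code{w_str * sum((u_v - y_v)^2) + sum((u_a - y_a)^2)}, summed over time
#' points, output units and (for lists) blocks. No averaging.
#'
#' @param outputs List with \code{u_v}, \code{u_a} matrices (or a list of
#'   such lists, one per block).
#' @param targets List with \code{y_v}, \code{y_a} matrices (or a list).
#' @param w_str Striatal weight (default 2).
#' @return Scalar loss.
#' @export
net_loss <- function(outputs, targets, w_str = 2) {
  one <- function(o, tg) {
    if (!all(dim(o$u_v) == dim(tg$y_v)) || !all(dim(o$u_a) == dim(tg$y_a))) {
      stop("output/target shape mismatch")
    }
    w_str * sum((o$u_v - tg$y_v)^2) + sum((o$u_a - tg$y_a)^2)
  }
  if (!is.null(outputs$u_v)) return(one(outputs, targets))
  stopifnot(length(outputs) == length(targets))
  sum(mapply(function(o, tg) one(o, tg), outputs, targets))
}

#' Loss gradient for one block via backpropagation through time
#'
#' Runs the forward pass over a block's tensors and accumulates the exact
#' reverse-mode gradient of the joint loss with respect to all six weight
#' matrices (through the readout coupling between the two networks).
#'
#' @param net A \code{corticostriatal_net}.
#' @param tensors A \code{\link{trial_tensors}} object.
#' @param w_str Striatal loss weight.
#' @param noise Inject white-noise input during the forward pass?
#' @return List with \code{loss} and gradients \code{gW_rr_s},
#'   \code{gW_ir_s}, \code{gW_ro_s}, \code{gW_rr_p}, \code{gW_ir_p},
#'   \code{gW_ro_p}, plus the forward outputs.
#' @export
net_gradient <- function(net, tensors, w_str = 2, noise = TRUE) {
  stopifnot(inherits(net, "corticostriatal_net"))
  Tn <- nrow(tensors$u_s)
  if (Tn == 0L) stop("empty tensors")
  eta <- net_noise(net, Tn, noise)
  rnn_bptt_cpp(net$W_rr_s, net$W_ir_s, net$W_ro_s,
               net$W_rr_p, net$W_ir_p, net$W_ro_p,
               tensors$u_s, tensors$u_ins, tensors$y_v, tensors$y_a,
               rep(0, net$n_s), rep(0, net$n_p),
               net$dt / net$tau, w_str, eta$s, eta$p)
}

.weight_names <- c("W_rr_s", "W_ir_s", "W_ro_s", "W_rr_p", "W_ir_p", "W_ro_p")

#' Train the network system
#'
#' Joint gradient training of both networks on encoded block tensors. At
#' every iteration a batch of \code{batch_k} blocks is drawn with
#' replacement from the training set, the BPTT gradient of the combined
#' loss is accumulated over the batch, and all six weight matrices are
#' updated. The learning rate follows the geometric outer-step schedule of
#' \code{\link{train_config}}. Throws an error (with the iteration index)
#' if the loss diverges to NaN.
#'
#' @param net A \code{corticostriatal_net} (untrained or to be refined).
#' @param dataset An \code{rnn_dataset} (its \code{train} list is used) or
#'   a plain list of \code{\link{trial_tensors}}.
#' @param cfg A \code{\link{train_config}}.
#' @param verbose Print progress per outer step?
#' @return The trained \code{corticostriatal_net}, with
#'   \code{loss_history} (data.frame: iteration, outer, lr, loss) attached
#'   and \code{trained = TRUE}.
#' @export
train_network <- function(net, dataset, cfg = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(net, "corticostriatal_net"),
            inherits(cfg, "train_config"))
  train <- if (inherits(dataset, "rnn_dataset")) dataset$train else dataset
  if (length(train) == 0L) stop("empty training set")

  ## Adam state
  m <- v <- lapply(net[.weight_names], function(W) W * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  total <- cfg$n_outer * cfg$iters_per_outer
  hist <- data.frame(iteration = seq_len(total), outer = 0L, lr = 0,
                     loss = NA_real_)
  it <- 0L
  for (k in seq_len(cfg$n_outer) - 1L) {
    lr <- cfg$lr0 * cfg$lr_decay^k
    for (j in seq_len(cfg$iters_per_outer)) {
      it <- it + 1L
      batch <- sample_batch(train, cfg$batch_k)
      grads <- NULL
      loss <- 0
      for (blk in batch) {
        g <- net_gradient(net, blk, w_str = cfg$striatal_weight, noise = TRUE)
        loss <- loss + g$loss
        if (is.null(grads)) {
          grads <- g[paste0("g", .weight_names)]
        } else {
          for (nm in .weight_names) {
            grads[[paste0("g", nm)]] <- grads[[paste0("g", nm)]] +
              g[[paste0("g", nm)]]
          }
        }
      }
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at iteration ", it,
             " (outer step ", k, ", lr ", lr, ")")
      }
      step <- step + 1L
      for (nm in .weight_names) {
        gr <- grads[[paste0("g", nm)]]
        if (cfg$optimizer == "adam") {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v[[nm]] / (1 - b2^step)
          net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        } else {
          net[[nm]] <- net[[nm]] - lr * gr
        }
      }
      hist$outer[it] <- k
      hist$lr[it] <- lr
      hist$loss[it] <- loss
    }
    if (verbose) {
      message(sprintf("outer %d/%d (lr %.2e): loss %.4g", k + 1L,
                      cfg$n_outer, lr, hist$loss[it]))
    }
  }
  net$trained <- TRUE
  net$loss_history <- if (is.null(net$loss_history)) hist else
    rbind(net$loss_history, hist)
  net
}

#' Test-set error as a function of trial in block
#'
#' Rolls the (teacher-forced) network over held-out test blocks and
#' computes the mean squared error between outputs and targets separately
#' for the prefrontal and striatal readouts, grouped by trial-in-block
#' index. After learning, the largest error sits on the first trial after
#' the sequence switch, when the correct sequence is not yet predictable,
#' and decreases across the block.
#'
#' @param net A trained \code{corticostriatal_net}.
#' @param dataset An \code{rnn_dataset} (its \code{test} list is used) or a
#'   list of \code{\link{trial_tensors}}.
#' @param noise Inject noise during the rollouts?
#' @return Data.frame with columns \code{trial}, \code{mse_prefrontal},
#'   \code{mse_striatal}, \code{n_blocks}.
#' @export
test_mse_by_trial <- function(net, dataset, noise = TRUE) {
  test <- if (inherits(dataset, "rnn_dataset")) dataset$test else dataset
  stopifnot(length(test) >= 1L)
  acc <- list()
  for (blk in test) {
    out <- net_rollout(net, blk, noise = noise)
    seg <- blk$segments
    trial_of_row <- rep(NA_integer_, nrow(blk$u_s))
    L <- blk$cfg$seg_len
    for (i in seq_len(nrow(seg))) {
      rows <- (seg$segment[i] * L) + seq_len(L)
      d <- seg$replays_decision[i]
      tr <- if (is.na(d)) 1L else blk$log$trial_index[d]
      trial_of_row[rows] <- min(tr, 8L)
    }
    se_p <- rowSums((out$u_a - blk$y_a)^2)
    se_s <- rowSums((out$u_v - blk$y_v)^2)
    for (tr in unique(trial_of_row)) {
      key <- as.character(tr)
      rows <- trial_of_row == tr
      cur <- acc[[key]] %||% c(0, 0, 0, 0)
      acc[[key]] <- cur + c(sum(se_p[rows]), sum(se_s[rows]),
                            sum(rows), 1)
    }
  }
  trials <- sort(as.integer(names(acc)))
  out <- do.call(rbind, lapply(trials, function(tr) {
    a <- acc[[as.character(tr)]]
    data.frame(trial = tr, mse_prefrontal = a[1] / (a[3] * 11),
               mse_striatal = a[2] / (a[3] * 10), n_blocks = a[4])
  }))
  rownames(out) <- NULL
  out
}
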