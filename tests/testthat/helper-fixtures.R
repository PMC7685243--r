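# Shared fixture builders. Everything is generated in code at test time.

# tiny random tensors with the right channel counts, for network-level tests
toy_tensors <- function(Tn, scale = 1) {
  list(u_s = matrix(rnorm(Tn * 15), Tn) * scale,
       u_ins = matrix(rnorm(Tn * 10), Tn) * scale,
       y_v = matrix(rnorm(Tn * 10), Tn) * scale,
       y_a = matrix(rnorm(Tn * 11), Tn) * scale)
}

# a hand-made dPCA model whose encoder/decoder are the identity on n units,
# so latent space == unit (rate) space; used by the dynamics oracles
identity_dpca <- function(n = 2L) {
  structure(list(F = list(s = diag(n)), D = list(s = diag(n)),
                 mean = rep(0, n), lambda = 0, dims = c(n, 1, 1, 1),
                 explained_variance = NULL),
            class = "dpca_model")
}

# a network with prescribed weights (zero by default) for closed-form checks
manual_net <- function(n_s = 2L, n_p = 2L, tau = 10, dt = 1, noise_sd = 0,
                       W_rr_s = NULL, W_ir_s = NULL) {
  net <- structure(list(
    W_rr_s = matrix(0, n_s, n_s), W_ir_s = matrix(0, n_s, 15),
    W_ro_s = matrix(0, 10, n_s), W_rr_p = matrix(0, n_p, n_p),
    W_ir_p = matrix(0, n_p, 20), W_ro_p = matrix(0, 11, n_p),
    n_s = n_s, n_p = n_p, g = 0, tau = tau, dt = dt, noise_sd = noise_sd,
    trained = FALSE, loss_history = NULL), class = "corticostriatal_net")
  if (!is.null(W_rr_s)) net$W_rr_s <- W_rr_s
  if (!is.null(W_ir_s)) net$W_ir_s <- W_ir_s
  net
}

# population tensor with planted structure:
# units x S x C x time = smooth time course + sequence offsets (rank-limited)
# + optional certainty-scaled separation + noise
planted_tensor <- function(n_units = 30L, S = 8L, C = 3L, Tn = 40L,
                           seq_rank = 3L, seq_scale = 1, cert_scale = 0,
                           noise_sd = 0.05) {
  tt <- seq(0, 2 * pi, length.out = Tn)
  base <- outer(rnorm(n_units), sin(tt))
  U <- qr.Q(qr(matrix(rnorm(n_units * seq_rank), n_units)))[, 1:seq_rank,
                                                            drop = FALSE]
  seq_load <- matrix(rnorm(seq_rank * S), seq_rank, S)
  seq_load <- seq_load - rowMeans(seq_load)     # pure sequence effect
  X <- array(0, c(n_units, S, C, Tn))
  for (s in 1:S) for (c in 1:C) {
    off <- U %*% seq_load[, s] * (seq_scale + cert_scale * (c - 1))
    X[, s, c, ] <- base + matrix(off, n_units, Tn) +
      rnorm(n_units * Tn, 0, noise_sd)
  }
  X
}
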