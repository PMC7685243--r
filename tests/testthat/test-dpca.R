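test_that("marginalization is an exact partition of the centered tensor", {
  set.seed(31)
  X <- array(rnorm(10 * 4 * 3 * 12), c(10, 4, 3, 12))
  m <- marginalize(X)
  recon <- m$mean + m$t + m$s + m$c + m$st + m$sc + m$ct + m$residual
  expect_lt(max(abs(recon - X)), 1e-10)
  # constant tensor: everything vanishes
  K <- array(3.7, c(5, 2, 2, 6))
  mk <- marginalize(K)
  for (phi in c("t", "s", "c", "st", "sc", "ct", "residual")) {
    expect_lt(max(abs(mk[[phi]])), 1e-12)
  }
  # pure time dependence: only the time marginalization survives
  Xt <- array(0, c(5, 2, 2, 6))
  tc <- matrix(rnorm(5 * 6), 5)
  for (s in 1:2) for (c in 1:2) Xt[, s, c, ] <- tc
  mt <- marginalize(Xt)
  expect_equal(mt$t + mt$mean, Xt, tolerance = 1e-12)
  for (phi in c("s", "c", "st", "sc", "ct", "residual")) {
    expect_lt(max(abs(mt[[phi]])), 1e-12)
  }
  expect_error(marginalize(matrix(0, 3, 3)), "4-d")
  Xna <- X; Xna[1] <- NA
  expect_error(marginalize(Xna), "unbalanced")
})

test_that("planted rank-3 sequence structure is recovered by 3 components", {
  set.seed(32)
  X <- planted_tensor(n_units = 30, seq_rank = 3, seq_scale = 1,
                      noise_sd = 0.02)
  fit <- fit_dpca(X, n_components = 5)
  ev <- fit$explained_variance
  top3 <- sum(ev$var_marginal[ev$marginalization == "s" & ev$component <= 3])
  expect_gt(top3, 0.99)
  # on label-shuffled data the sequence components capture far less of the
  # total variance
  Xs <- X[, sample(8), , ]
  dim(Xs) <- dim(X)
  tot_planted <- sum(ev$var_total[ev$marginalization == "s" & ev$component <= 3])
  # destroy sequence structure by averaging the planted offsets away:
  Xnull <- X
  for (c_i in 1:3) {
    mu <- apply(X[, , c_i, ], c(1, 3), mean)
    for (s_i in 1:8) Xnull[, s_i, c_i, ] <- mu +
        array(rnorm(30 * 40, 0, 0.02), c(30, 40))
  }
  evn <- fit_dpca(Xnull, n_components = 5)$explained_variance
  tot_null <- sum(evn$var_total[evn$marginalization == "s" & evn$component <= 3])
  expect_gt(tot_planted, 10 * tot_null)
})

test_that("with lambda = 0 the fit matches an independently computed reduced-rank regression", {
  set.seed(33)
  X <- planted_tensor(n_units = 12, S = 4, C = 2, Tn = 20, seq_rank = 2,
                      noise_sd = 0.1)
  fit <- fit_dpca(X, n_components = 2, lambda = 0)
  # independent oracle: ordinary least squares + SVD truncation
  m <- marginalize(X)
  Xc <- matrix(X - m$mean, 12)
  Xphi <- matrix(m$s, 12)
  B <- Xphi %*% t(Xc) %*% solve(Xc %*% t(Xc))
  fitted <- B %*% Xc
  sv <- svd(fitted)
  P <- sv$u[, 1:2]
  recon_oracle <- P %*% t(P) %*% fitted
  recon_fit <- fit$F[["s"]] %*% fit$D[["s"]] %*% Xc
  expect_equal(recon_fit, recon_oracle, tolerance = 1e-8)
  # zero components: reconstruction is zero
  f0 <- fit_dpca(X, n_components = c(t = 1, s = 0, c = 1, st = 0, sc = 0,
                                     ct = 0))
  expect_equal(ncol(f0$F[["s"]]), 0L)
  expect_error(fit_dpca(X, n_components = 50), "rank")
})

test_that("projection is linear, smoothing-optional, and inverts the encoder", {
  set.seed(34)
  X <- planted_tensor(n_units = 20, noise_sd = 0.05)
  fit <- fit_dpca(X, n_components = 3)
  tr <- X[, 1, 1, ]
  z0 <- dpca_project(tr, fit, d = 3, sigma = 0)
  expect_equal(z0, t(fit$D[["s"]][1:3, ] %*% (tr - fit$mean)),
               tolerance = 1e-12)
  # the encoder columns are orthonormal, and on noise-free data projecting
  # the model's own reconstruction recovers D X
  Xnf <- planted_tensor(n_units = 20, noise_sd = 0)
  fnf <- fit_dpca(Xnf, n_components = 3)
  expect_equal(crossprod(fnf$F[["s"]]), diag(3), tolerance = 1e-10)
  trn <- Xnf[, 1, 1, ]
  Dx <- fnf$D[["s"]] %*% (trn - fnf$mean)
  recon <- fnf$F[["s"]] %*% Dx + fnf$mean
  expect_equal(dpca_project(recon, fnf, d = 3, sigma = 0), t(Dx[1:3, ]),
               tolerance = 1e-3)
  # constant trace projects to a constant point
  zc <- dpca_project(matrix(0.5, 20, 10), fit, d = 2, sigma = 2)
  expect_lt(max(apply(zc, 2, sd)), 1e-12)
  expect_error(dpca_project(tr, fit, sigma = -1), "sigma")
})

test_that("inter-sequence distance obeys closed forms and rotation invariance", {
  set.seed(35)
  X <- array(0, c(6, 3, 2, 15))
  base <- matrix(rnorm(6 * 15), 6)
  for (s in 1:3) for (c in 1:2) X[, s, c, ] <- base
  d0 <- inter_sequence_distance(X)
  expect_equal(d0$curve$distance, c(0, 0))
  # constant offset: distance of the shifted pair equals the offset norm
  v <- rnorm(6)
  X2 <- X; for (c in 1:2) X2[, 2, c, ] <- base + v
  d2 <- inter_sequence_distance(X2)
  expect_equal(unname(d2$pairs["1-2", ]), rep(sqrt(sum(v^2)), 2),
               tolerance = 1e-12)
  # invariance under a global rotation of unit space
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  X3 <- X2
  for (s in 1:3) for (c in 1:2) X3[, s, c, ] <- Q %*% X2[, s, c, ]
  d3 <- inter_sequence_distance(X3)
  expect_equal(d3$pairs, d2$pairs, tolerance = 1e-10)
  expect_error(inter_sequence_distance(X, clusters = list(1L)), "at least 2")
})

test_that("distance-to-centroid compactness matches geometry", {
  X <- array(0, c(2, 2, 1, 16))
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  X[1, 1, 1, ] <- cos(th); X[2, 1, 1, ] <- sin(th)   # unit circle
  X[, 2, 1, ] <- 0.3                                  # constant point
  cc <- centroid_compactness(X)
  expect_equal(cc$sequences[1, 1], 1, tolerance = 1e-10)
  expect_equal(cc$sequences[2, 1], 0, tolerance = 1e-12)
  expect_error(centroid_compactness(array(0, c(2, 2, 1, 1))), ">= 2")
})

test_that("hemifield separation is detected when planted and calibrated under the null", {
  set.seed(36)
  hemi <- rep(c("upper", "lower"), each = 4)
  make_X <- function(sep) {
    X <- array(rnorm(10 * 8 * 2 * 12, 0, 0.3), c(10, 8, 2, 12))
    for (s in 1:8) {
      X[1, s, , ] <- X[1, s, , ] + ifelse(hemi[s] == "upper", sep, -sep)
    }
    X
  }
  res <- hemifield_separation_test(make_X(3), hemi)
  expect_true(all(res$p_bonferroni < 1e-3))
  expect_true(all(res$between > res$within))
  # under shuffled labels the test is calibrated: the false-positive rate
  # at alpha = 0.05 stays near 0.05 and p-values are not skewed (a KS test
  # is unsuitable here because only 70 distinct label partitions exist)
  X0 <- make_X(0)
  ps <- replicate(200, {
    hemifield_separation_test(X0, sample(hemi))$p[1]
  })
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_error(hemifield_separation_test(make_X(1), rep("upper", 8)),
               "both hemifields")
})
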