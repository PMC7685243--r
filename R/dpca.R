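## Demixed principal component analysis: exact factorial marginalization of
## a population tensor over time / sequence / certainty, followed by
## ridge-regularized reduced-rank regression per marginalization.
##
## The population tensor is a 4-d array units x sequences x certainty x
## time. Marginalization is the ANOVA-style variance decomposition: the
## centered tensor is split exactly into main effects (t, s, c), pairwise
## interactions (sc, st, ct) and a residual (the three-way interaction,
## playing the role of the noise term).

.dpca_phis <- c("t", "s", "c", "st", "sc", "ct")

## mean over the axes NOT in `keep` (subset of c(2,3,4)), broadcast back to
## full shape. Axis 1 (units) is always kept.
.mean_keep <- function(X, keep) {
  d <- dim(X)
  keep <- sort(unique(c(1L, keep)))
  m <- apply(X, keep, mean)
  ## broadcast back
  perm <- c(keep, setdiff(1:4, keep))
  full <- array(m, dim = c(d[keep], d[setdiff(1:4, keep)]))
  aperm(full, order(perm))
}

#' Marginalize a population tensor over task parameters
#'
#' Decomposes a balanced units x sequences x certainty x time tensor into
#' the exact factorial effects of time (\code{t}), sequence (\code{s}),
#' certainty (\code{c}) and their pairwise interactions (\code{st},
#' \code{sc}, \code{ct}), plus the residual three-way term. The pieces sum
#' to the centered tensor exactly (machine precision).
#'
#' @param X Numeric 4-d array, units x sequences x certainty x time, with
#'   no missing cells.
#' @return A list with the grand-mean-per-unit array \code{mean}, one array
#'   per marginalization (\code{t}, \code{s}, \code{c}, \code{st},
#'   \code{sc}, \code{ct}), and \code{residual}.
#' @export
marginalize <- function(X) {
  if (!is.array(X) || length(dim(X)) != 4L) {
    stop("X must be a 4-d array: units x sequences x certainty x time")
  }
  if (anyNA(X)) stop("unbalanced tensor: missing cells after averaging")
  axes <- list(t = 4L, s = 2L, c = 3L,
               st = c(2L, 4L), sc = c(2L, 3L), ct = c(3L, 4L))
  gm <- .mean_keep(X, integer(0))            # per-unit grand mean
  Xc <- X - gm
  out <- list(mean = gm)
  ## main effects
  for (phi in c("t", "s", "c")) {
    out[[phi]] <- .mean_keep(Xc, axes[[phi]])
  }
  ## pairwise interactions: subtract the contained main effects
  main_in <- list(st = c("s", "t"), sc = c("s", "c"), ct = c("c", "t"))
  for (phi in c("st", "sc", "ct")) {
    m <- .mean_keep(Xc, axes[[phi]])
    for (sub in main_in[[phi]]) m <- m - out[[sub]]
    out[[phi]] <- m
  }
  out$residual <- Xc - Reduce(`+`, out[.dpca_phis])
  out
}

.flatten <- function(A) {
  d <- dim(A)
  matrix(A, d[1], prod(d[-1]))
}

#' Fit a demixed PCA model
#'
#' For every marginalization, finds an encoder/decoder pair (F, D) of the
#' requested rank minimizing ||X_phi - F D X||^2 by ridge-regularized
#' reduced-rank regression: the full-rank ridge regression of X_phi on the
#' centered data X is computed in closed form and its fitted values are
#' truncated by SVD. The decoder rows are the demixed principal components.
#'
#' @param X Population tensor (units x sequences x certainty x time).
#' @param n_components Components per marginalization: a single number or a
#'   named vector over \code{c("t","s","c","st","sc","ct")}.
#' @param lambda Ridge penalty; default \code{1e-6 * sum(X^2)}.
#' @return An object of class \code{dpca_model}: per-marginalization
#'   encoders \code{F[[phi]]} (units x q), decoders \code{D[[phi]]}
#'   (q x units), the per-unit mean, and an explained-variance table.
#' @export
fit_dpca <- function(X, n_components = 10L, lambda = NULL) {
  marg <- marginalize(X)
  n_units <- dim(X)[1]
  Xc <- .flatten(X - marg$mean)
  if (is.null(lambda)) lambda <- 1e-6 * sum(X^2)
  if (is.null(names(n_components))) {
    n_components <- stats::setNames(rep(n_components[1], length(.dpca_phis)),
                                    .dpca_phis)
  }
  G <- Xc %*% t(Xc) + lambda * diag(n_units)
  Ginv <- solve(G)
  total_var <- sum(Xc^2)
  enc <- dec <- list()
  evar <- NULL
  for (phi in .dpca_phis) {
    q <- as.integer(n_components[[phi]])
    if (q > n_units) stop("rank ", q, " exceeds the number of units for ", phi)
    Xphi <- .flatten(marg[[phi]])
    B <- Xphi %*% t(Xc) %*% Ginv          # full-rank ridge solution
    if (q == 0L) {
      enc[[phi]] <- matrix(0, n_units, 0)
      dec[[phi]] <- matrix(0, 0, n_units)
      next
    }
    fitted <- B %*% Xc
    sv <- svd(fitted, nu = q, nv = 0)
    P <- sv$u                              # units x q
    enc[[phi]] <- P
    dec[[phi]] <- t(P) %*% B
    comp <- dec[[phi]] %*% Xc              # q x conditions
    evar <- rbind(evar, data.frame(
      marginalization = phi,
      component = seq_len(q),
      var_marginal = rowSums(comp^2) / max(sum(Xphi^2), .Machine$double.eps),
      var_total = rowSums(comp^2) / total_var))
  }
  structure(list(F = enc, D = dec, mean = marg$mean[, 1, 1, 1],
                 lambda = lambda, dims = dim(X),
                 explained_variance = evar),
            class = "dpca_model")
}

#' @export
print.dpca_model <- function(x, ...) {
  cat(sprintf("<dpca_model> %d units, %d sequences x %d certainty x %d time\n",
              x$dims[1], x$dims[2], x$dims[3], x$dims[4]))
  ev <- x$explained_variance
  top <- ev[ev$component <= 3, ]
  agg <- stats::aggregate(var_marginal ~ marginalization, top, sum)
  cat("  marginal variance in first 3 components:\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("    %-3s %.1f%%\n", agg$marginalization[i],
                100 * agg$var_marginal[i]))
  }
  invisible(x)
}

#' Gaussian smoothing along time
#'
#' Smooths each row of a units x time matrix with a Gaussian kernel of the
#' given SD (in time bins), renormalizing the kernel at the edges.
#'
#' @param X Units x time matrix.
#' @param sigma Kernel SD in bins; \code{0} returns \code{X} unchanged.
#' @return Smoothed matrix of the same shape.
#' @export
gauss_smooth <- function(X, sigma = 2) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(X)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  Tn <- ncol(X)
  out <- X
  for (t in seq_len(Tn)) {
    lo <- max(1L, t - half); hi <- min(Tn, t + half)
    kk <- k[(lo - t + half + 1L):(hi - t + half + 1L)]
    kk <- kk / sum(kk)
    out[, t] <- X[, lo:hi, drop = FALSE] %*% kk
  }
  out
}

#' Project population activity into a demixed latent space
#'
#' Gaussian-smooths a units x time trace, removes the per-unit mean stored
#' in the model, and projects onto the leading decoder rows of the chosen
#' marginalization (the sequence subspace by default).
#'
#' @param X Units x time matrix of population activity.
#' @param model A fitted \code{\link{fit_dpca}} model.
#' @param phi Marginalization whose decoder to use.
#' @param d Number of latent dimensions.
#' @param sigma Gaussian smoothing SD in time bins (0 = no smoothing).
#' @return Time x d matrix of latent trajectories.
#' @export
dpca_project <- function(X, model, phi = "s", d = 3L, sigma = 2) {
  stopifnot(inherits(model, "dpca_model"))
  D <- model$D[[phi]]
  if (is.null(D)) stop("unknown marginalization: ", phi)
  d <- min(d, nrow(D))
  Xs <- gauss_smooth(X, sigma) - model$mean
  t(D[seq_len(d), , drop = FALSE] %*% Xs)
}

#' Mean Euclidean distance between sequence trajectories
#'
#' For each certainty level, computes the Euclidean distance between the
#' trajectories of every sequence pair, averaged across time points, and
#' averages over pairs. When a cluster partition is given (e.g. the
#' upper/lower hemifield split used for prefrontal data), only
#' within-cluster pairs enter. Distances are computed in the space the
#' tensor lives in (full unit space, or a reduced dPC space if the tensor
#' was projected first).
#'
#' @param X Population tensor (units x sequences x certainty x time).
#' @param clusters Optional list of integer vectors of sequence indices
#'   defining the clusters; \code{NULL} uses all pairs.
#' @return A list: \code{curve} (data.frame certainty x mean distance) and
#'   \code{pairs} (matrix of per-pair time-averaged distances, pairs x
#'   certainty) for paired tests.
#' @export
inter_sequence_distance <- function(X, clusters = NULL) {
  stopifnot(is.array(X), length(dim(X)) == 4L)
  S <- dim(X)[2]; C <- dim(X)[3]
  if (is.null(clusters)) clusters <- list(seq_len(S))
  pairs <- do.call(rbind, lapply(clusters, function(cl) {
    if (length(cl) < 2L) stop("need at least 2 sequences per cluster")
    t(utils::combn(cl, 2L))
  }))
  pd <- matrix(NA_real_, nrow(pairs), C)
  for (c_i in seq_len(C)) {
    for (p in seq_len(nrow(pairs))) {
      A <- X[, pairs[p, 1], c_i, ]; B <- X[, pairs[p, 2], c_i, ]
      pd[p, c_i] <- mean(sqrt(colSums((A - B)^2)))
    }
  }
  curve <- data.frame(certainty = seq_len(C), distance = colMeans(pd))
  rownames(pd) <- apply(pairs, 1, paste, collapse = "-")
  list(curve = curve, pairs = pd)
}

#' Distance-to-centroid compactness of sequence trajectories
#'
#' A sequence's centroid is the mean across time of its trajectory; the
#' compactness statistic is the Euclidean distance of every time point to
#' the centroid, averaged across time and then across sequences, per
#' certainty level. Trajectories that contract with learning show this
#' measure decreasing.
#'
#' @inheritParams inter_sequence_distance
#' @return A list: \code{curve} (certainty x mean distance-to-centroid) and
#'   \code{sequences} (per-sequence matrix, sequences x certainty).
#' @export
centroid_compactness <- function(X) {
  stopifnot(is.array(X), length(dim(X)) == 4L)
  S <- dim(X)[2]; C <- dim(X)[3]
  if (dim(X)[4] < 2L) stop("trajectory length must be >= 2")
  m <- matrix(NA_real_, S, C)
  for (c_i in seq_len(C)) {
    for (s_i in seq_len(S)) {
      A <- X[, s_i, c_i, ]
      cen <- rowMeans(A)
      m[s_i, c_i] <- mean(sqrt(colSums((A - cen)^2)))
    }
  }
  list(curve = data.frame(certainty = seq_len(C),
                          distance_to_centroid = colMeans(m)),
       sequences = m)
}

#' Test for separation of trajectories by visual hemifield
#'
#' For every sequence, compares its mean trajectory distance to
#' same-hemifield sequences against its mean distance to other-hemifield
#' sequences with a paired t-test, per certainty level, Bonferroni
#' correcting over levels.
#'
#' @param X Population tensor (units x sequences x certainty x time) or a
#'   d x sequences x certainty x time latent array.
#' @param hemifield Character vector over sequences (\code{"upper"} /
#'   \code{"lower"}).
#' @return Data.frame with one row per certainty level: mean within- and
#'   between-hemifield distances, t statistic, raw and Bonferroni p.
#' @export
hemifield_separation_test <- function(X, hemifield) {
  stopifnot(is.array(X), length(dim(X)) == 4L,
            length(hemifield) == dim(X)[2])
  if (length(unique(hemifield)) < 2L) {
    stop("both hemifields must be represented")
  }
  S <- dim(X)[2]; C <- dim(X)[3]
  res <- NULL
  for (c_i in seq_len(C)) {
    D <- matrix(0, S, S)
    for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
      d <- mean(sqrt(colSums((X[, i, c_i, ] - X[, j, c_i, ])^2)))
      D[i, j] <- D[j, i] <- d
    }
    within <- between <- numeric(S)
    for (i in seq_len(S)) {
      same <- which(hemifield == hemifield[i]); same <- setdiff(same, i)
      diff <- which(hemifield != hemifield[i])
      within[i] <- mean(D[i, same])
      between[i] <- mean(D[i, diff])
    }
    tt <- stats::t.test(between, within, paired = TRUE)
    res <- rbind(res, data.frame(
      certainty = c_i, within = mean(within), between = mean(between),
      t = unname(tt$statistic), p = tt$p.value))
  }
  res$p_bonferroni <- pmin(1, res$p * C)
  res
}
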