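## Canonical correlation analysis between two population datasets (model
## vs. reference): Gaussian smoothing, dimensionality reduction, CCA via
## SVD of the whitened cross-covariance, and the associated significance
## machinery (sequential Wilks-lambda tests; Fisher z comparison of
## coefficient sets).

## PCA reduction of a units x time matrix to d dimensions (scores d x T).
.pca_reduce <- function(X, d) {
  Xc <- X - rowMeans(X)
  sv <- svd(Xc, nu = min(d, nrow(Xc)), nv = 0)
  if (sum(sv$d > max(sv$d) * 1e-10) < d) {
    stop("rank deficiency after reduction: data has rank ",
         sum(sv$d > max(sv$d) * 1e-10), " < ", d)
  }
  t(sv$u[, seq_len(d), drop = FALSE]) %*% Xc
}

#' Canonical correlations between two population datasets
#'
#' Both datasets (units x time, already trial-averaged) are smoothed with a
#' Gaussian kernel, reduced to \code{d_reduce} dimensions (so that CCA is
#' not performed along directions of high correlation but negligible
#' variance), and the leading \code{n_cc} canonical correlation
#' coefficients are extracted by SVD of the ridge-whitened cross-covariance
#' over the shared time axis.
#'
#' @param X,Y Units x time matrices with identical time axes (unit counts
#'   may differ).
#' @param d_reduce Dimensionality of the reduction (default 15).
#' @param n_cc Number of canonical coefficients (default 10).
#' @param sigma Gaussian smoothing SD in time bins.
#' @param ridge Whitening ridge (relative to the mean eigenvalue).
#' @return An object of class \code{cca_result}: \code{cor} (length
#'   \code{n_cc}, non-increasing, in [0, 1]), canonical variable time
#'   series \code{xvar}, \code{yvar} (n_cc x T), and \code{n} (time
#'   samples).
#' @export
cca_compare <- function(X, Y, d_reduce = 15L, n_cc = 10L, sigma = 2,
                        ridge = 1e-10) {
  stopifnot(is.matrix(X), is.matrix(Y), ncol(X) == ncol(Y))
  Tn <- ncol(X)
  if (nrow(X) < d_reduce || nrow(Y) < d_reduce) {
    stop("each dataset needs at least d_reduce = ", d_reduce, " units")
  }
  if (Tn <= d_reduce) stop("time axis too short for d_reduce = ", d_reduce)
  n_cc <- min(n_cc, d_reduce)
  A <- .pca_reduce(gauss_smooth(X, sigma), d_reduce)
  B <- .pca_reduce(gauss_smooth(Y, sigma), d_reduce)
  A <- A - rowMeans(A); B <- B - rowMeans(B)
  Saa <- A %*% t(A) / (Tn - 1); Sbb <- B %*% t(B) / (Tn - 1)
  Sab <- A %*% t(B) / (Tn - 1)
  whiten <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    vals <- e$values + ridge * mean(e$values)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  Wa <- whiten(Saa); Wb <- whiten(Sbb)
  M <- Wa %*% Sab %*% Wb
  sv <- svd(M)
  r <- pmin(pmax(sv$d[seq_len(n_cc)], 0), 1)
  xvar <- t(sv$u[, seq_len(n_cc), drop = FALSE]) %*% Wa %*% A
  yvar <- t(sv$v[, seq_len(n_cc), drop = FALSE]) %*% Wb %*% B
  structure(list(cor = r, xvar = xvar, yvar = yvar, n = Tn,
                 d_reduce = d_reduce),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> %d coefficients over %d time samples (reduced to %d dims)\n",
              length(x$cor), x$n, x$d_reduce))
  cat("  ", paste(sprintf("%.3f", x$cor), collapse = " "), "\n")
  cat(sprintf("  mean coefficient: %.3f\n", mean(x$cor)))
  invisible(x)
}

#' Sequential significance of canonical correlations (Wilks lambda)
#'
#' Bartlett's sequential chi-square approximation: for each k, tests
#' whether canonical correlations k+1, ... are jointly zero via
#' \eqn{\Lambda_k = \prod_{i>k} (1 - r_i^2)}.
#'
#' @param cca A \code{cca_result} (or a numeric vector of coefficients,
#'   with \code{n} and \code{p}, \code{q} supplied).
#' @param n Number of samples (taken from the result if omitted).
#' @param p,q Dimensionalities of the two reduced datasets.
#' @return Data.frame with one row per coefficient: \code{r},
#'   \code{wilks}, \code{chisq}, \code{df}, \code{p_value}.
#' @export
cca_significance <- function(cca, n = NULL, p = NULL, q = NULL) {
  if (inherits(cca, "cca_result")) {
    r <- cca$cor
    n <- n %||% cca$n
    p <- p %||% cca$d_reduce
    q <- q %||% cca$d_reduce
  } else {
    r <- cca
    if (is.null(n) || is.null(p) || is.null(q)) {
      stop("supply n, p and q with a bare coefficient vector")
    }
  }
  if (n < p + q + 2) warning("sample size too small for the asymptotic test")
  m <- length(r)
  out <- data.frame(k = seq_len(m), r = r, wilks = NA_real_,
                    chisq = NA_real_, df = NA_integer_, p_value = NA_real_)
  for (k in seq_len(m)) {
    lam <- prod(1 - r[k:m]^2)
    chi <- -(n - 1 - (p + q + 1) / 2) * log(max(lam, .Machine$double.xmin))
    df <- (p - k + 1) * (q - k + 1)
    out$wilks[k] <- lam
    out$chisq[k] <- chi
    out$df[k] <- df
    out$p_value[k] <- stats::pchisq(chi, df, lower.tail = FALSE)
  }
  out
}

#' Compare two sets of canonical coefficients (Fisher z)
#'
#' Per-coefficient two-sample comparison after Fisher's z-transformation,
#' e.g. trained vs. untrained model coefficients against the same
#' reference.
#'
#' @param r1,r2 Coefficient vectors of equal length.
#' @param n1,n2 Sample sizes behind each set.
#' @return Data.frame with \code{z} statistics and two-sided
#'   \code{p_value}s per coefficient.
#' @export
fisher_z_compare <- function(r1, r2, n1, n2 = n1) {
  stopifnot(length(r1) == length(r2), n1 > 3, n2 > 3)
  clip <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- (atanh(clip(r1)) - atanh(clip(r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  data.frame(k = seq_along(r1), r1 = r1, r2 = r2, z = z,
             p_value = 2 * stats::pnorm(-abs(z)))
}

## trial-averaged rates of one network over repeated noisy rollouts of the
## same block tensors.
.avg_rates <- function(net, tensors, area, n_rep) {
  xfield <- if (area == "prefrontal") "x_p" else "x_s"
  acc <- NULL
  for (i in seq_len(n_rep)) {
    out <- net_rollout(net, tensors, noise = TRUE, record_states = TRUE)
    r <- tanh(t(out[[xfield]]))
    acc <- if (is.null(acc)) r else acc + r
  }
  acc / n_rep
}

#' Trained vs. untrained model similarity to a reference population
#'
#' Runs a trained and an architecture-matched untrained network over the
#' same input tensors (averaging rates across repeated noisy rollouts, the
#' model analogue of trial averaging), compares each to the reference
#' dataset with \code{\link{cca_compare}}, and reports both coefficient
#' spectra, their means, and the per-coefficient Fisher-z comparison.
#'
#' @param trained,untrained \code{corticostriatal_net} objects.
#' @param reference Units x time reference matrix (e.g. recorded data, or
#'   a surrogate population) with the same time axis as the tensors.
#' @param tensors \code{\link{trial_tensors}} of the comparison block.
#' @param area Which network's activity to compare.
#' @param n_rep Rollout repetitions averaged per model.
#' @param ... Passed to \code{\link{cca_compare}}.
#' @return List with \code{trained}, \code{untrained} (both
#'   \code{cca_result}), \code{mean_trained}, \code{mean_untrained}, and
#'   the Fisher-z \code{comparison} table.
#' @export
trained_vs_untrained <- function(trained, untrained, reference, tensors,
                                 area = c("prefrontal", "striatal"),
                                 n_rep = 10L, ...) {
  area <- match.arg(area)
  stopifnot(ncol(reference) == nrow(tensors$u_s))
  Xt <- .avg_rates(trained, tensors, area, n_rep)
  Xu <- .avg_rates(untrained, tensors, area, n_rep)
  ct <- cca_compare(Xt, reference, ...)
  cu <- cca_compare(Xu, reference, ...)
  list(trained = ct, untrained = cu,
       mean_trained = mean(ct$cor), mean_untrained = mean(cu$cor),
       comparison = fisher_z_compare(ct$cor, cu$cor, ct$n, cu$n))
}
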