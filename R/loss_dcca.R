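# DCCA: canonical correlations of a minibatch pair, computed as singular
# values of T = S11^{-1/2} S12 S22^{-1/2} with diagonally loaded within-view
# covariances; the loss is minus the sum of the top-C correlations.

# Symmetric inverse square root via eigendecomposition; errors when the
# loaded covariance is not positive definite (degenerate batch).
sym_inv_sqrt <- function(S, label) {
  es <- eigen(S, symmetric = TRUE)
  if (any(es$values <= 0)) {
    stop("cca_correlations: ", label,
         " covariance is not positive definite after regularization; ",
         "batch is numerically degenerate")
  }
  es$vectors %*% (t(es$vectors) / sqrt(es$values))
}

# Shared core: covariances, T, its SVD, and everything the gradient needs.
cca_core <- function(vp, params) {
  stopifnot(inherits(vp, "view_pair"), inherits(params, "dcca_params"))
  n <- vp$n
  d <- vp$d
  if (n <= 2L) {
    stop("cca_correlations: need more than 2 samples for a covariance ",
         "estimate (got n = ", n, ")")
  }
  if (n <= d) {
    stop("cca_correlations: batch size n = ", n, " must exceed the ",
         "embedding dimensionality d = ", d, " for a full-rank covariance")
  }
  if (params$C > d) {
    stop("cca_correlations: C = ", params$C, " exceeds embedding ",
         "dimensionality d = ", d)
  }
  H1 <- sweep(vp$Z, 2L, colMeans(vp$Z))
  H2 <- sweep(vp$Zp, 2L, colMeans(vp$Zp))
  if (all(abs(H1) < 1e-12) || all(abs(H2) < 1e-12)) {
    stop("cca_correlations: a view is constant across the batch; ",
         "canonical correlations are undefined")
  }
  S11 <- crossprod(H1) / (n - 1) + diag(params$rx, d)
  S22 <- crossprod(H2) / (n - 1) + diag(params$ry, d)
  S12 <- crossprod(H1, H2) / (n - 1)
  R1 <- sym_inv_sqrt(S11, "first-view")
  R2 <- sym_inv_sqrt(S22, "second-view")
  Tm <- R1 %*% S12 %*% R2
  sv <- svd(Tm)
  list(H1 = H1, H2 = H2, R1 = R1, R2 = R2, sv = sv, n = n, d = d)
}

#' Canonical correlations of a paired embedding batch
#'
#' Computes the top-`C` canonical correlations between the two views of a
#' [view_pair()] from the regularized within- and cross-view covariance
#' matrices (diagonal loading `rx`, `ry`), together with the per-pair
#' coefficient vectors.
#'
#' @param vp a [view_pair()].
#' @param params a [dcca_params()].
#' @return An object of class `cca_result`: `correlations` (length `C`,
#'   non-increasing, in `[0, 1]` up to numerical tolerance), `coef_x` and
#'   `coef_y` (d x C coefficient matrices, one canonical pair per column)
#'   and `C`.
#' @export
cca_correlations <- function(vp, params = dcca_params(C = min(10L, ncol(vp$Z)))) {
  core <- cca_core(vp, params)
  C <- params$C
  idx <- seq_len(C)
  structure(
    list(correlations = pmin(pmax(core$sv$d[idx], 0), 1 + 1e-8),
         coef_x = core$R1 %*% core$sv$u[, idx, drop = FALSE],
         coef_y = core$R2 %*% core$sv$v[, idx, drop = FALSE],
         C = C),
    class = "cca_result"
  )
}

#' DCCA alignment loss
#'
#' Minus the sum of the top-`C` canonical correlations of the pair, so that
#' minimizing the loss maximizes total canonical correlation. The value
#' lies in `[-C, 0]`. With `grad = TRUE` the analytic gradients with
#' respect to both views are returned; they follow the standard matrix
#' calculus for singular values of `T = S11^{-1/2} S12 S22^{-1/2}`.
#'
#' @param vp a [view_pair()] holding projector outputs for the two views.
#' @param params a [dcca_params()].
#' @param grad if `TRUE`, also return gradients `dZ` and `dZp`.
#' @return If `grad = FALSE`, the scalar loss. Otherwise a list with
#'   `value`, `dZ` and `dZp`.
#' @export
dcca_loss <- function(vp, params = dcca_params(C = min(10L, ncol(vp$Z))),
                      grad = FALSE) {
  core <- cca_core(vp, params)
  C <- params$C
  idx <- seq_len(C)
  value <- -sum(core$sv$d[idx])
  if (!grad) return(value)
  U <- core$sv$u[, idx, drop = FALSE]
  V <- core$sv$v[, idx, drop = FALSE]
  D <- core$sv$d[idx]
  # d(sum of top-C singular values)/dT = U V'; pull back through the
  # covariance construction (Andrew et al.'s DCCA backward pass).
  nab12 <- core$R1 %*% U %*% t(V) %*% core$R2
  nab11 <- -0.5 * core$R1 %*% U %*% (D * t(U)) %*% core$R1
  nab22 <- -0.5 * core$R2 %*% V %*% (D * t(V)) %*% core$R2
  dcorr_dZ <- (2 * core$H1 %*% nab11 + core$H2 %*% t(nab12)) / (core$n - 1)
  dcorr_dZp <- (2 * core$H2 %*% nab22 + core$H1 %*% nab12) / (core$n - 1)
  list(value = value, dZ = -dcorr_dZ, dZp = -dcorr_dZp)
}
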