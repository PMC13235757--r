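# VICReg: invariance (mean squared pairwise distance), variance (hinge on
# per-dimension spread towards a target gamma) and covariance (off-diagonal
# suppression of the n-1-normalized sample covariance), weighted alpha/mu/nu.

vicreg_variance_term <- function(Zc, n, d, params) {
  v <- colSums(Zc^2) / (n - 1)
  if (params$variance_hinge == "std") {
    s <- sqrt(v + params$eps)
    term <- pmax(0, params$gamma - s)
    list(value = sum(term) / d, var = v, std = s, active = term > 0)
  } else {
    term <- pmax(0, params$gamma - v + params$eps)
    list(value = sum(term) / d, var = v, std = sqrt(v + params$eps),
         active = term > 0)
  }
}

vicreg_variance_grad <- function(Zc, vt, n, d, params) {
  # d var_j / d z_ij = 2 zc_ij / (n - 1); hinge gates inactive columns
  if (params$variance_hinge == "std") {
    coef <- ifelse(vt$active, -1 / (2 * vt$std * d), 0)
  } else {
    coef <- ifelse(vt$active, -1 / d, 0)
  }
  cg <- coef * 2 / (n - 1)
  sweep(Zc, 2L, cg, `*`)
}

vicreg_cov_term <- function(Zc, n, d) {
  Cm <- crossprod(Zc) / (n - 1)
  off <- Cm
  diag(off) <- 0
  list(value = sum(off^2) / d, C = Cm, off = off)
}

#' VICReg alignment loss with component breakdown
#'
#' Returns the three VICReg components and their weighted total for a
#' paired embedding batch: invariance `s` (mean squared row distance),
#' variance `v(Z) + v(Zp)` (per-dimension hinge towards the target spread
#' `gamma`) and covariance `c(Z) + c(Zp)` (sum of squared off-diagonal
#' sample-covariance entries, scaled by `1/d`). The total is
#' `alpha * s + mu * (v(Z) + v(Zp)) + nu * (c(Z) + c(Zp))`, exactly.
#'
#' @param vp a [view_pair()].
#' @param params a [vicreg_params()].
#' @param grad if `TRUE`, also return analytic gradients `dZ` and `dZp` of
#'   the weighted total.
#' @return An object of class `vicreg_breakdown` with elements
#'   `invariance`, `variance`, `covariance`, `total` (and `dZ`, `dZp` when
#'   `grad = TRUE`).
#' @export
vicreg_loss <- function(vp, params = vicreg_params(), grad = FALSE) {
  stopifnot(inherits(vp, "view_pair"), inherits(params, "vicreg_params"))
  n <- vp$n
  d <- vp$d
  if (n < 2L) stop("vicreg_loss: need n >= 2 for sample variance")
  Z <- vp$Z
  Zp <- vp$Zp
  inv <- sum((Z - Zp)^2) / n
  Zc <- sweep(Z, 2L, colMeans(Z))
  Zpc <- sweep(Zp, 2L, colMeans(Zp))
  vt1 <- vicreg_variance_term(Zc, n, d, params)
  vt2 <- vicreg_variance_term(Zpc, n, d, params)
  ct1 <- vicreg_cov_term(Zc, n, d)
  ct2 <- vicreg_cov_term(Zpc, n, d)
  variance <- vt1$value + vt2$value
  covariance <- ct1$value + ct2$value
  total <- params$alpha * inv + params$mu * variance + params$nu * covariance
  out <- structure(
    list(invariance = inv, variance = variance, covariance = covariance,
         total = total),
    class = "vicreg_breakdown"
  )
  if (!grad) return(out)
  dinv <- (2 / n) * (Z - Zp)
  g1 <- params$mu * vicreg_variance_grad(Zc, vt1, n, d, params) +
    params$nu * (2 / d) * (Zc %*% (2 * ct1$off)) / (n - 1)
  g2 <- params$mu * vicreg_variance_grad(Zpc, vt2, n, d, params) +
    params$nu * (2 / d) * (Zpc %*% (2 * ct2$off)) / (n - 1)
  # centering adjoint: subtract column means of the centered-space gradient
  g1 <- sweep(g1, 2L, colMeans(g1))
  g2 <- sweep(g2, 2L, colMeans(g2))
  out$dZ <- params$alpha * dinv + g1
  out$dZp <- -params$alpha * dinv + g2
  out
}

#' @export
print.vicreg_breakdown <- function(x, ...) {
  cat(sprintf(
    "<vicreg_breakdown> invariance %.4g  variance %.4g  covariance %.4g  total %.4g\n",
    x$invariance, x$variance, x$covariance, x$total))
  invisible(x)
}
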