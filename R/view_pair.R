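#' Paired two-view embedding batch
#'
#' Bundles two same-shape embedding matrices whose rows are matched: row
#' `i` of `Z` (the model view) and row `i` of `Zp` (the brain view) are the
#' two representations of the same stimulus, i.e. a positive pair. Every
#' alignment loss in the package consumes this container.
#'
#' @param Z numeric matrix, n x d, first-view embeddings (one row per sample).
#' @param Zp numeric matrix, n x d, second-view embeddings, row-matched to `Z`.
#' @return An object of class `view_pair` with elements `Z`, `Zp`, `n`, `d`
#'   and `zbar` (the column means of `Z`).
#' @examples
#' vp <- view_pair(matrix(rnorm(20), 5), matrix(rnorm(20), 5))
#' vp$n; vp$d
#' @export
view_pair <- function(Z, Zp) {
  Z <- as.matrix(Z)
  Zp <- as.matrix(Zp)
  if (!is.numeric(Z) || !is.numeric(Zp)) {
    stop("view_pair: both views must be numeric matrices")
  }
  if (!all(dim(Z) == dim(Zp))) {
    stop("view_pair: Z and Zp must have identical dimensions (got ",
         paste(dim(Z), collapse = "x"), " vs ",
         paste(dim(Zp), collapse = "x"), ")")
  }
  if (nrow(Z) < 2L) stop("view_pair: need at least 2 samples (rows)")
  if (ncol(Z) < 1L) stop("view_pair: need at least 1 embedding dimension")
  structure(
    list(Z = Z, Zp = Zp, n = nrow(Z), d = ncol(Z), zbar = colMeans(Z)),
    class = "view_pair"
  )
}

#' @export
print.view_pair <- function(x, ...) {
  cat("<view_pair> n =", x$n, " d =", x$d, "\n")
  invisible(x)
}

#' Hyperparameters for the DCCA alignment loss
#'
#' `C` is the number of canonical pairs whose correlations are summed in
#' the loss; `rx` and `ry` are small diagonal loadings added to the
#' within-view covariance matrices so their inverse square roots exist at
#' minibatch scale.
#'
#' @param C number of canonical pairs (default 10, the projector output
#'   width, i.e. all pairs).
#' @param rx,ry positive diagonal covariance regularizers (default 1e-3).
#' @return An object of class `dcca_params`.
#' @export
dcca_params <- function(C = 10L, rx = 1e-3, ry = 1e-3) {
  C <- as.integer(C)
  if (C < 1L) stop("dcca_params: C must be >= 1")
  if (rx <= 0 || ry <= 0) stop("dcca_params: rx and ry must be > 0")
  structure(list(C = C, rx = rx, ry = ry), class = "dcca_params")
}

#' Hyperparameters for the InfoNCE (NT-Xent) alignment loss
#'
#' @param tau positive softmax temperature (default 0.5).
#' @return An object of class `infonce_params`.
#' @export
infonce_params <- function(tau = 0.5) {
  if (tau <= 0) stop("infonce_params: tau must be > 0")
  structure(list(tau = tau), class = "infonce_params")
}

#' Hyperparameters for the VICReg alignment loss
#'
#' Component weights follow the invariance/variance/covariance ordering;
#' `gamma` is the target per-dimension standard deviation in the variance
#' hinge and `eps` the stabilizer inside its square root. The default
#' weights (2, 2, 1) and `eps = 1e-4` are the values used throughout the
#' co-training experiments.
#'
#' @param alpha,mu,nu non-negative weights for the invariance, variance and
#'   covariance components.
#' @param gamma positive target standard deviation (default 1).
#' @param eps small positive variance stabilizer (default 1e-4).
#' @param variance_hinge `"std"` (default) hinges on the regularized
#'   standard deviation, `max(0, gamma - sqrt(Var + eps))`; `"var"` hinges
#'   on the variance directly, `max(0, gamma - Var + eps)`.
#' @return An object of class `vicreg_params`.
#' @export
vicreg_params <- function(alpha = 2, mu = 2, nu = 1, gamma = 1, eps = 1e-4,
                          variance_hinge = c("std", "var")) {
  variance_hinge <- match.arg(variance_hinge)
  if (alpha < 0 || mu < 0 || nu < 0) {
    stop("vicreg_params: component weights must be >= 0")
  }
  if (gamma <= 0) stop("vicreg_params: gamma must be > 0")
  if (eps <= 0) stop("vicreg_params: eps must be > 0")
  structure(list(alpha = alpha, mu = mu, nu = nu, gamma = gamma, eps = eps,
                 variance_hinge = variance_hinge),
            class = "vicreg_params")
}
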