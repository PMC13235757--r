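# InfoNCE in its NT-Xent form: the 2n model and brain embeddings are pooled,
# each matched (model_i, brain_i) pair is a positive, and every other pooled
# sample is a negative under a temperature-scaled cosine-similarity softmax.

#' InfoNCE (NT-Xent) alignment loss
#'
#' Pools the `2n` embeddings of both views, and for every positive pair
#' computes the cross-entropy of the cosine-similarity softmax at
#' temperature `tau` against the `2n - 1` other pooled samples. The loss is
#' averaged over all `2n` positive-pair orderings and is non-negative.
#' When all embeddings are identical it equals `log(2n - 1)`, the uniform-
#' softmax ceiling.
#'
#' @param vp a [view_pair()].
#' @param params an [infonce_params()].
#' @param grad if `TRUE`, also return analytic gradients `dZ` and `dZp`.
#' @return If `grad = FALSE`, the scalar loss; otherwise a list with
#'   `value`, `dZ`, `dZp`.
#' @export
infonce_loss <- function(vp, params = infonce_params(), grad = FALSE) {
  stopifnot(inherits(vp, "view_pair"), inherits(params, "infonce_params"))
  n <- vp$n
  if (n < 2L) stop("infonce_loss: need n >= 2 (no negatives otherwise)")
  E <- rbind(vp$Z, vp$Zp)                    # 2n x d pooled embeddings
  m <- 2L * n
  nrm <- sqrt(rowSums(E^2))
  if (any(nrm == 0)) {
    stop("infonce_loss: zero-norm embedding row(s) ",
         paste(which(nrm == 0), collapse = ", "),
         "; cosine similarity is undefined")
  }
  U <- E / nrm
  S <- tcrossprod(U) / params$tau            # s_ij = cos(e_i, e_j) / tau
  diag(S) <- -Inf                            # k != i in the partition sum
  pos <- c((n + 1L):m, 1L:n)                 # positive index of each row
  # log-softmax per row, numerically stable
  rmax <- apply(S, 1L, max)
  Sexp <- exp(S - rmax)
  rsum <- rowSums(Sexp)
  P <- Sexp / rsum
  value <- mean(rmax + log(rsum) - S[cbind(seq_len(m), pos)])
  if (!grad) return(value)
  G <- P / m                                 # dL/ds_ij from row i
  G[cbind(seq_len(m), pos)] <- G[cbind(seq_len(m), pos)] - 1 / m
  diag(G) <- 0
  dU <- ((G + t(G)) %*% U) / params$tau
  # chain through row normalization u = e / ||e||
  dE <- (dU - U * rowSums(dU * U)) / nrm
  list(value = value,
       dZ = dE[seq_len(n), , drop = FALSE],
       dZp = dE[(n + 1L):m, , drop = FALSE])
}
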