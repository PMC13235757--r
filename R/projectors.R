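# Projector heads for alignment: two independent MLPs of identical shape,
# f_x on flattened backbone features and f_y on raw per-site neural
# responses, mapping both views into a shared low-dimensional space.

mlp_build <- function(din, width, out_dim, depth = 3L) {
  sizes <- c(din, rep(width, depth), out_dim)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    dense_layer(sizes[i], sizes[i + 1L], init = "normal", sd = 0.01)
  })
}

#' Build an independent projector pair
#'
#' Each projector is a 3-layer perceptron (hidden width `width`, ReLU
#' activations) followed by dropout and a final linear layer of width
#' `out_dim`. The two networks share no parameters. All weights are drawn
#' from Normal(0, 0.01) deterministically from the seed; biases start at
#' zero. Dropout is active only in training mode.
#'
#' @param input_dim_x flattened backbone feature width for the model view.
#' @param input_dim_y number of neural sites for the brain view.
#' @param seed integer seed fixing the initialization.
#' @param width hidden width (default 1024).
#' @param out_dim output width of the shared alignment space (default 10).
#' @param dropout dropout probability after the last hidden layer
#'   (default 0.5).
#' @return An object of class `projector_pair` with elements `f_x`, `f_y`,
#'   `width`, `out_dim`, `dropout`.
#' @export
build_projectors <- function(input_dim_x, input_dim_y, seed,
                             width = 1024L, out_dim = 10L, dropout = 0.5) {
  stopifnot(input_dim_x >= 1L, input_dim_y >= 1L, width >= 1L, out_dim >= 1L)
  with_seed(derive_seed(seed, "projector_init"), {
    structure(list(
      f_x = mlp_build(input_dim_x, width, out_dim),
      f_y = mlp_build(input_dim_y, width, out_dim),
      width = as.integer(width), out_dim = as.integer(out_dim),
      dropout = dropout
    ), class = "projector_pair")
  })
}

# Forward one projector over a row-batch X (n x din). Dropout (train mode)
# masks the last hidden activation with inverted scaling.
mlp_forward <- function(layers, X, dropout = 0, train = FALSE) {
  a <- t(X)  # din x n, column per sample
  nh <- length(layers) - 1L
  cache <- list(inputs = vector("list", length(layers)))
  for (i in seq_len(nh)) {
    cache$inputs[[i]] <- a
    a <- relu_forward(dense_forward(layers[[i]], a))
    cache$acts[[i]] <- a
  }
  if (train && dropout > 0) {
    mask <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a))
    a <- a * mask / (1 - dropout)
    cache$mask <- mask
  }
  cache$inputs[[nh + 1L]] <- a
  out <- dense_forward(layers[[nh + 1L]], a)
  cache$dropout <- if (train) dropout else 0
  list(out = t(out), cache = cache)
}

mlp_backward <- function(layers, cache, dout) {
  nh <- length(layers) - 1L
  g <- t(dout)
  grads <- vector("list", length(layers))
  bl <- dense_backward(layers[[nh + 1L]], cache$inputs[[nh + 1L]], g)
  grads[[nh + 1L]] <- list(dW = bl$dW, db = bl$db)
  g <- bl$dx
  if (!is.null(cache$mask)) {
    g <- g * cache$mask / (1 - cache$dropout)
  }
  for (i in rev(seq_len(nh))) {
    g <- relu_backward(cache$acts[[i]], g)
    bl <- dense_backward(layers[[i]], cache$inputs[[i]], g)
    grads[[i]] <- list(dW = bl$dW, db = bl$db)
    g <- bl$dx
  }
  list(grads = grads, dX = t(g))
}

#' Project both views of a paired batch into the alignment space
#'
#' @param pp a [build_projectors()] pair.
#' @param X model-view features (n x input_dim_x).
#' @param Y brain-view responses (n x input_dim_y).
#' @param train enable dropout.
#' @return A list with the projected [view_pair()] and forward caches.
#' @export
project_views <- function(pp, X, Y, train = FALSE) {
  fx <- mlp_forward(pp$f_x, X, dropout = pp$dropout, train = train)
  fy <- mlp_forward(pp$f_y, Y, dropout = pp$dropout, train = train)
  list(vp = view_pair(fx$out, fy$out), cache_x = fx$cache, cache_y = fy$cache)
}
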