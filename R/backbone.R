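# CORnet-Z style backbone: four named convolutional blocks (V1, V2, V4, IT),
# each conv -> ReLU -> max-pool, followed by a global-average-pool + linear
# decoder. Block outputs are tappable by name so intermediate representations
# can be aligned with neural recordings from the corresponding cortical area.

BLOCK_ORDER <- c("V1", "V2", "V4", "IT")

#' Backbone architecture specification
#'
#' The `cornet_z` variant follows the published CORnet-Z layout (7x7
#' stride-2 V1 convolution, 3x3 convolutions elsewhere, 3x3 stride-2
#' max-pools, widths 64/128/256/512). The `tiny` variant keeps the block
#' names, order and tap contracts but uses narrow 3x3 stride-1 blocks with
#' 2x2 pools (widths 8/16/16/32); it exists for desk-scale experiments and
#' tests.
#'
#' @param variant `"cornet_z"` or `"tiny"`.
#' @param num_classes number of output classes for the classification head.
#' @param input_size input image side length in pixels (square images).
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(variant = c("cornet_z", "tiny"),
                          num_classes = 100L, input_size = 32L) {
  variant <- match.arg(variant)
  layers <- if (variant == "cornet_z") {
    list(
      V1 = list(cout = 64L,  k = 7L, s = 2L, p = 3L, pool = c(3L, 2L, 1L)),
      V2 = list(cout = 128L, k = 3L, s = 1L, p = 1L, pool = c(3L, 2L, 1L)),
      V4 = list(cout = 256L, k = 3L, s = 1L, p = 1L, pool = c(3L, 2L, 1L)),
      IT = list(cout = 512L, k = 3L, s = 1L, p = 1L, pool = c(3L, 2L, 1L))
    )
  } else {
    list(
      V1 = list(cout = 8L,  k = 3L, s = 1L, p = 1L, pool = c(2L, 2L, 0L)),
      V2 = list(cout = 16L, k = 3L, s = 1L, p = 1L, pool = c(2L, 2L, 0L)),
      V4 = list(cout = 16L, k = 3L, s = 1L, p = 1L, pool = c(2L, 2L, 0L)),
      IT = list(cout = 32L, k = 3L, s = 1L, p = 1L, pool = c(2L, 2L, 0L))
    )
  }
  # trace spatial sizes through the cascade
  h <- as.integer(input_size)
  sizes <- list()
  for (bn in BLOCK_ORDER) {
    ly <- layers[[bn]]
    h <- conv_out_hw(h, ly$k, ly$s, ly$p)
    if (h < 1L) stop("backbone_spec: input_size ", input_size,
                     " collapses to nothing at block ", bn)
    h <- conv_out_hw(h, ly$pool[1], ly$pool[2], ly$pool[3])
    if (h < 1L) stop("backbone_spec: input_size ", input_size,
                     " collapses to nothing at block ", bn, " pool")
    sizes[[bn]] <- h
  }
  structure(list(variant = variant, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size), layers = layers,
                 out_hw = sizes),
            class = "backbone_spec")
}

#' Build a backbone with seed-deterministic Xavier-uniform initialization
#'
#' Repeated calls with the same seed produce bit-identical parameters.
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed fixing the initialization.
#' @return An object of class `backbone` holding block convolution
#'   parameters, the decoder, and per-block flattened feature widths
#'   (`feature_dims`).
#' @export
build_backbone <- function(spec, seed) {
  stopifnot(inherits(spec, "backbone_spec"))
  with_seed(derive_seed(seed, "backbone_init"), {
    cin <- 3L
    blocks <- list()
    dims <- integer(0)
    for (bn in BLOCK_ORDER) {
      ly <- spec$layers[[bn]]
      blocks[[bn]] <- c(conv_layer(cin, ly$cout, ly$k, ly$s, ly$p,
                                   init = "xavier"),
                        list(pool = ly$pool))
      hw <- spec$out_hw[[bn]]
      dims[bn] <- hw * hw * ly$cout
      cin <- ly$cout
    }
    decoder <- dense_layer(cin, spec$num_classes, init = "xavier")
    structure(list(spec = spec, blocks = blocks, decoder = decoder,
                   feature_dims = dims),
              class = "backbone")
  })
}

#' @export
print.backbone <- function(x, ...) {
  cat("<backbone ", x$spec$variant, "> blocks: ",
      paste(sprintf("%s[%d]", names(x$feature_dims), x$feature_dims),
            collapse = " -> "),
      " -> decoder[", x$spec$num_classes, "]\n", sep = "")
  invisible(x)
}

# Forward through blocks up to and including `upto` (NULL = all blocks +
# decoder). Returns taps (raw arrays) and, when keep_cache, everything the
# backward pass needs.
backbone_forward <- function(bb, images, upto = NULL, keep_cache = FALSE) {
  x <- images
  if (length(dim(x)) != 4L) stop("backbone_forward: images must be H x W x C x N")
  taps <- list()
  caches <- list()
  for (bn in BLOCK_ORDER) {
    blk <- bb$blocks[[bn]]
    cf <- conv_forward(blk, x, keep_cache = keep_cache)
    a <- relu_forward(cf$y)
    pl <- maxpool_forward(a, blk$pool[1], blk$pool[2], blk$pool[3])
    if (keep_cache) {
      caches[[bn]] <- list(conv = cf$cache, act = a, argmax = pl$argmax,
                           adim = dim(a))
    }
    x <- pl$y
    taps[[bn]] <- x
    if (!is.null(upto) && bn == upto) {
      return(list(taps = taps, caches = caches, top = x, logits = NULL))
    }
  }
  feat <- gap_forward(x)
  logits <- dense_forward(bb$decoder, feat)
  if (keep_cache) {
    caches$decoder <- list(feat = feat, itdim = dim(x))
  }
  list(taps = taps, caches = caches, top = x, logits = logits)
}

zero_like_backbone <- function(bb) {
  g <- list(blocks = lapply(bb$blocks, function(blk) {
    list(dW = matrix(0, nrow(blk$W), ncol(blk$W)), db = numeric(length(blk$b)))
  }))
  g$decoder <- list(dW = matrix(0, nrow(bb$decoder$W), ncol(bb$decoder$W)),
                    db = numeric(length(bb$decoder$b)))
  g
}

# Backward through the backbone. dlogits (K x N) drives the decoder path;
# dtaps is a named list of gradients w.r.t. flattened block taps (n x p
# matrices). Alignment gradients enter at their tap and flow only through
# the prefix, which is exactly what a scoped co-training step requires.
backbone_backward <- function(bb, fw, dlogits = NULL, dtaps = list()) {
  grads <- zero_like_backbone(bb)
  dtop <- NULL
  if (!is.null(dlogits)) {
    dec <- dense_backward(bb$decoder, fw$caches$decoder$feat, dlogits)
    grads$decoder$dW <- grads$decoder$dW + dec$dW
    grads$decoder$db <- grads$decoder$db + dec$db
    dtop <- gap_backward(dec$dx, fw$caches$decoder$itdim)
  }
  for (bn in rev(BLOCK_ORDER)) {
    if (is.null(fw$caches[[bn]])) next  # forward stopped before this block
    cache <- fw$caches[[bn]]
    dpool <- dtop
    if (!is.null(dtaps[[bn]])) {
      extra <- unflatten_tap(dtaps[[bn]], dim(fw$taps[[bn]]))
      dpool <- if (is.null(dpool)) extra else dpool + extra
    }
    if (is.null(dpool)) next
    blk <- bb$blocks[[bn]]
    da <- maxpool_backward(cache$argmax, dpool, cache$adim)
    dconv <- relu_backward(cache$act, da)
    cb <- conv_backward(blk, cache$conv, dconv, need_dx = (bn != "V1"))
    grads$blocks[[bn]]$dW <- grads$blocks[[bn]]$dW + cb$dW
    grads$blocks[[bn]]$db <- grads$blocks[[bn]]$db + cb$db
    dtop <- cb$dx
  }
  grads
}

#' Extract flattened block features for a batch of images
#'
#' Runs the backbone forward in eval mode up to the named block and returns
#' its post-activation, post-pool feature map flattened to one row per
#' image (width `channels * height * width` of the tapped block).
#'
#' @param backbone a [build_backbone()] result.
#' @param images array `H x W x C x N` of preprocessed images.
#' @param block one of `"V1"`, `"V2"`, `"V4"`, `"IT"`.
#' @return Numeric matrix, `N x p`.
#' @export
extract_block_features <- function(backbone, images, block) {
  if (!block %in% BLOCK_ORDER) {
    stop("extract_block_features: unknown block '", block,
         "' (expected one of ", paste(BLOCK_ORDER, collapse = ", "), ")")
  }
  fw <- backbone_forward(backbone, images, upto = block, keep_cache = FALSE)
  flatten_tap(fw$taps[[block]])
}

#' Predict class labels in eval mode
#'
#' @param backbone a [build_backbone()] result.
#' @param images array `H x W x C x N`.
#' @param batch_size evaluation minibatch size.
#' @return Integer vector of predicted labels (1-based).
#' @export
predict_classes <- function(backbone, images, batch_size = 256L) {
  n <- dim(images)[4]
  out <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- backbone_forward(backbone, images[, , , i:j, drop = FALSE])
    out[i:j] <- apply(fw$logits, 2L, which.max)
    i <- j + 1L
  }
  out
}
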