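# Optimizers over nested parameter/gradient trees (lists of numeric
# arrays). The backbone uses SGD with momentum; the projector heads use
# RMSprop, each with their own L2 weight decay, matching the co-training
# recipe (SGD momentum 0.9, lr 1e-3, wd 1e-4; RMSprop lr 1e-4, wd 1e-5).

tree_leaves_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_leaves_map2, a, b, MoreArgs = list(f = f),
                  SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

tree_add <- function(a, b) tree_leaves_map2(a, b, `+`)

sgd_momentum <- function(lr = 1e-3, momentum = 0.9, weight_decay = 1e-4) {
  structure(list(lr = lr, momentum = momentum, wd = weight_decay,
                 state = NULL),
            class = "sgd_momentum")
}

rmsprop <- function(lr = 1e-4, alpha = 0.99, eps = 1e-8,
                    weight_decay = 1e-5) {
  structure(list(lr = lr, alpha = alpha, eps = eps, wd = weight_decay,
                 state = NULL),
            class = "rmsprop")
}

optim_step <- function(opt, params, grads) UseMethod("optim_step")

#' @export
optim_step.sgd_momentum <- function(opt, params, grads) {
  if (is.null(opt$state)) opt$state <- tree_zero(params)
  g <- tree_leaves_map2(grads, params, function(gr, th) gr + opt$wd * th)
  opt$state <- tree_leaves_map2(opt$state, g,
                                function(v, gr) opt$momentum * v + gr)
  params <- tree_leaves_map2(params, opt$state,
                             function(th, v) th - opt$lr * v)
  list(opt = opt, params = params)
}

#' @export
optim_step.rmsprop <- function(opt, params, grads) {
  if (is.null(opt$state)) opt$state <- tree_zero(params)
  g <- tree_leaves_map2(grads, params, function(gr, th) gr + opt$wd * th)
  opt$state <- tree_leaves_map2(
    opt$state, g, function(s, gr) opt$alpha * s + (1 - opt$alpha) * gr^2)
  upd <- tree_leaves_map2(g, opt$state,
                          function(gr, s) gr / (sqrt(s) + opt$eps))
  params <- tree_leaves_map2(params, upd,
                             function(th, u) th - opt$lr * u)
  list(opt = opt, params = params)
}

# Pack backbone params/grads into matching trees so one optimizer call
# updates every conv and decoder weight.
backbone_params <- function(bb) {
  c(lapply(bb$blocks, function(blk) list(W = blk$W, b = blk$b)),
    list(decoder = list(W = bb$decoder$W, b = bb$decoder$b)))
}

backbone_set_params <- function(bb, tree) {
  for (bn in names(bb$blocks)) {
    bb$blocks[[bn]]$W <- tree[[bn]]$W
    bb$blocks[[bn]]$b <- tree[[bn]]$b
  }
  bb$decoder$W <- tree$decoder$W
  bb$decoder$b <- tree$decoder$b
  bb
}

backbone_grads_tree <- function(g) {
  c(lapply(g$blocks, function(x) list(W = x$dW, b = x$db)),
    list(decoder = list(W = g$decoder$dW, b = g$decoder$db)))
}

projector_params <- function(pp) {
  list(f_x = lapply(pp$f_x, function(l) list(W = l$W, b = l$b)),
       f_y = lapply(pp$f_y, function(l) list(W = l$W, b = l$b)))
}

projector_set_params <- function(pp, tree) {
  for (i in seq_along(pp$f_x)) {
    pp$f_x[[i]]$W <- tree$f_x[[i]]$W
    pp$f_x[[i]]$b <- tree$f_x[[i]]$b
  }
  for (i in seq_along(pp$f_y)) {
    pp$f_y[[i]]$W <- tree$f_y[[i]]$W
    pp$f_y[[i]]$b <- tree$f_y[[i]]$b
  }
  pp
}

projector_grads_tree <- function(gx, gy) {
  list(f_x = lapply(gx, function(l) list(W = l$dW, b = l$db)),
       f_y = lapply(gy, function(l) list(W = l$dW, b = l$db)))
}
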