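# Joint optimization of classification cross-entropy plus lambda-weighted
# per-block alignment losses, with scoped backpropagation (each alignment
# term flows only through the projectors and the backbone prefix up to its
# block), dual optimizers, matched-seed experiment management and the
# shuffled-pairing control.

ALIGN_BLOCKS <- c("V1", "V4", "IT")
LAMBDA_GRID <- c(0, 0.1, 0.25, 0.5, 0.75, 0.9)

#' Stimulus-response set
#'
#' Pairs an ordered stimulus image collection with a per-site response
#' matrix for one cortical area. `pairing` is a permutation over stimulus
#' indices: stimulus `i` is paired with response row `pairing[i]`. The
#' identity permutation is the correct pairing; [shuffle_pairing()]
#' replaces it with a random one while preserving the response rows
#' exactly.
#'
#' @param stimuli array `H x W x C x N` of stimulus images.
#' @param responses numeric matrix `N x S` (stimulus by recording site).
#' @param area one of `"V1"`, `"V4"`, `"IT"`.
#' @param pairing integer permutation of `1:N` (default identity).
#' @return An object of class `stimulus_response_set`.
#' @export
stimulus_response_set <- function(stimuli, responses, area,
                                  pairing = seq_len(nrow(responses))) {
  if (!area %in% ALIGN_BLOCKS) {
    stop("stimulus_response_set: area must be one of ",
         paste(ALIGN_BLOCKS, collapse = ", "))
  }
  n <- dim(stimuli)[4]
  if (nrow(responses) != n) {
    stop("stimulus_response_set: ", n, " stimuli but ",
         nrow(responses), " response rows")
  }
  if (!identical(sort(as.integer(pairing)), seq_len(n))) {
    stop("stimulus_response_set: pairing must be a permutation of 1..", n)
  }
  structure(list(stimuli = stimuli, responses = responses, area = area,
                 pairing = as.integer(pairing), n = n,
                 sites = ncol(responses)),
            class = "stimulus_response_set")
}

#' @export
print.stimulus_response_set <- function(x, ...) {
  cat("<stimulus_response_set ", x$area, "> ", x$n, " stimuli x ",
      x$sites, " sites; pairing ",
      if (identical(x$pairing, seq_len(x$n))) "identity" else "permuted",
      "\n", sep = "")
  invisible(x)
}

#' Shuffled-pairing control
#'
#' Returns a copy of the set whose pairing is a uniformly random
#' permutation drawn deterministically from `seed`. The stimuli and the
#' multiset of response rows are unchanged; only which response goes with
#' which stimulus is destroyed. This is the control condition that keeps
#' the response distribution while removing stimulus-response structure.
#'
#' @param srs a [stimulus_response_set()].
#' @param seed integer seed for the permutation.
#' @return A [stimulus_response_set()] with permuted `pairing`.
#' @export
shuffle_pairing <- function(srs, seed) {
  stopifnot(inherits(srs, "stimulus_response_set"))
  perm <- with_seed(derive_seed(seed, "shuffle_pairing"),
                    sample.int(srs$n))
  stimulus_response_set(srs$stimuli, srs$responses, srs$area, pairing = perm)
}

#' Alignment specification: which blocks, which loss, how strongly
#'
#' @param lambda_by_block named non-negative weights for `"V1"`, `"V4"`,
#'   `"IT"`; blocks with weight 0 are not aligned. A weight of 0 for all
#'   blocks defines the baseline model (pure cross-entropy training).
#' @param loss_kind one of `"dcca"`, `"infonce"`, `"vicreg"`.
#' @param loss_params the matching parameter object ([dcca_params()],
#'   [infonce_params()] or [vicreg_params()]); defaults to that
#'   constructor's defaults.
#' @param grid_check if `TRUE`, require every lambda to come from the
#'   experimental grid `{0, 0.1, 0.25, 0.5, 0.75, 0.9}`.
#' @return An object of class `alignment_spec`.
#' @export
alignment_spec <- function(lambda_by_block = c(V1 = 0, V4 = 0, IT = 0),
                           loss_kind = c("dcca", "infonce", "vicreg"),
                           loss_params = NULL, grid_check = FALSE) {
  loss_kind <- match.arg(loss_kind)
  lb <- c(V1 = 0, V4 = 0, IT = 0)
  lb[names(lambda_by_block)] <- lambda_by_block
  if (any(lb < 0)) stop("alignment_spec: lambda weights must be >= 0")
  if (grid_check && !all(lb %in% LAMBDA_GRID)) {
    stop("alignment_spec: in grid mode lambdas must come from {",
         paste(LAMBDA_GRID, collapse = ", "), "}")
  }
  if (is.null(loss_params)) {
    loss_params <- switch(loss_kind,
                          dcca = dcca_params(),
                          infonce = infonce_params(),
                          vicreg = vicreg_params())
  }
  structure(list(lambda_by_block = lb, loss_kind = loss_kind,
                 loss_params = loss_params),
            class = "alignment_spec")
}

aligned_blocks <- function(spec) {
  names(spec$lambda_by_block)[spec$lambda_by_block > 0]
}

#' Evaluate one alignment loss on a projected view pair
#'
#' Dispatches to [dcca_loss()], [infonce_loss()] or [vicreg_loss()]
#' according to `spec$loss_kind`; always returns a scalar `value` (for VICReg, the
#' weighted total) plus gradients when requested.
#'
#' @param vp a [view_pair()].
#' @param spec an [alignment_spec()].
#' @param grad if `TRUE`, include `dZ` and `dZp`.
#' @return List with `value` (and `dZ`, `dZp` when `grad = TRUE`).
#' @export
alignment_loss <- function(vp, spec, grad = FALSE) {
  switch(spec$loss_kind,
    dcca = {
      r <- dcca_loss(vp, spec$loss_params, grad = grad)
      if (grad) r else list(value = r)
    },
    infonce = {
      r <- infonce_loss(vp, spec$loss_params, grad = grad)
      if (grad) r else list(value = r)
    },
    vicreg = {
      r <- vicreg_loss(vp, spec$loss_params, grad = grad)
      list(value = r$total, dZ = r$dZ, dZp = r$dZp, breakdown = r)
    })
}

#' Combined co-training loss
#'
#' `L_total = sum_block lambda_block * L_align_block + L_ce`, exactly.
#' Blocks with zero weight contribute nothing and need no alignment value.
#'
#' @param ce scalar cross-entropy loss.
#' @param align named list/vector of per-block alignment losses (entries
#'   required for every block with positive lambda).
#' @param spec an [alignment_spec()].
#' @return An object of class `loss_breakdown` with `ce`, `align` (named,
#'   weight > 0 blocks) and `total`.
#' @export
combined_loss <- function(ce, align, spec) {
  blocks <- aligned_blocks(spec)
  missing <- setdiff(blocks, names(align))
  if (length(missing)) {
    stop("combined_loss: missing alignment value for block(s) with ",
         "positive lambda: ", paste(missing, collapse = ", "))
  }
  av <- vapply(blocks, function(b) as.numeric(align[[b]]), numeric(1))
  total <- ce + sum(spec$lambda_by_block[blocks] * av)
  structure(list(ce = ce, align = as.list(av) |> stats::setNames(blocks),
                 total = total),
            class = "loss_breakdown")
}

#' Training configuration
#'
#' Captures the optimization recipe: SGD with momentum 0.9, learning rate
#' 1e-3 and L2 weight decay 1e-4 for the backbone; RMSprop with learning
#' rate 1e-4 and weight decay 1e-5 for the projector heads; classification
#' batches of 256 and neural batches of 50; a 10% validation holdout. One
#' seed jointly controls backbone initialization, projector initialization,
#' data ordering, augmentation and dropout draws, through independent
#' derived streams (see [derive_seed()]).
#'
#' @param epochs number of training epochs.
#' @param seed master seed of the run.
#' @param variant backbone variant (see [backbone_spec()]).
#' @param num_classes classification classes.
#' @param input_size image side length.
#' @param class_batch classification minibatch size (default 256).
#' @param neural_batch neural minibatch size (default 50).
#' @param val_fraction validation fraction used when a task carries no
#'   explicit validation split (default 0.1).
#' @param backbone_lr,backbone_momentum,backbone_wd backbone SGD settings.
#' @param projector_lr,projector_wd projector RMSprop settings.
#' @param projector_width,projector_out,projector_dropout projector shape.
#' @param augment apply random-crop (4-pixel padding) + horizontal-flip
#'   augmentation to classification training batches.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, seed, variant = "cornet_z",
                         num_classes = 100L, input_size = 32L,
                         class_batch = 256L, neural_batch = 50L,
                         val_fraction = 0.1,
                         backbone_lr = 1e-3, backbone_momentum = 0.9,
                         backbone_wd = 1e-4,
                         projector_lr = 1e-4, projector_wd = 1e-5,
                         projector_width = 1024L, projector_out = 10L,
                         projector_dropout = 0.5,
                         augment = TRUE) {
  structure(list(epochs = as.integer(epochs), seed = as.integer(seed),
                 variant = variant, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 class_batch = as.integer(class_batch),
                 neural_batch = as.integer(neural_batch),
                 val_fraction = val_fraction,
                 backbone_lr = backbone_lr,
                 backbone_momentum = backbone_momentum,
                 backbone_wd = backbone_wd,
                 projector_lr = projector_lr, projector_wd = projector_wd,
                 projector_width = as.integer(projector_width),
                 projector_out = as.integer(projector_out),
                 projector_dropout = projector_dropout,
                 augment = augment),
            class = "train_config")
}

# Initialize a full training state (backbone, per-block projector pairs,
# optimizers) from a config + spec + neural site counts.
init_train_state <- function(cfg, spec, neural_sets) {
  bspec <- backbone_spec(cfg$variant, cfg$num_classes, cfg$input_size)
  bb <- build_backbone(bspec, cfg$seed)
  projectors <- list()
  opt_proj <- list()
  for (bn in aligned_blocks(spec)) {
    srs <- neural_sets[[bn]]
    if (is.null(srs)) {
      stop("init_train_state: lambda > 0 for block ", bn,
           " but no stimulus-response set of that area was supplied")
    }
    projectors[[bn]] <- build_projectors(
      input_dim_x = bb$feature_dims[[bn]],
      input_dim_y = srs$sites,
      seed = derive_seed(cfg$seed, paste0("proj_", bn)),
      width = cfg$projector_width, out_dim = cfg$projector_out,
      dropout = cfg$projector_dropout)
    opt_proj[[bn]] <- rmsprop(lr = cfg$projector_lr,
                              weight_decay = cfg$projector_wd)
  }
  list(backbone = bb, projectors = projectors,
       opt_backbone = sgd_momentum(lr = cfg$backbone_lr,
                                   momentum = cfg$backbone_momentum,
                                   weight_decay = cfg$backbone_wd),
       opt_proj = opt_proj, step = 0L)
}

#' One co-training step
#'
#' Computes the classification cross-entropy on the class batch through the
#' full network and, for each aligned block, extracts that block's features
#' for the neural stimuli, projects both views, and evaluates the alignment
#' loss. The alignment gradient enters the backbone at the block's tap and
#' therefore flows only through the projectors and the backbone prefix up
#' to and including that block — parameters downstream of the tap receive
#' exactly zero gradient from the alignment term. One SGD step (backbone)
#' and one RMSprop step (each projector pair) are applied on the
#' accumulated gradients of the combined loss.
#'
#' @param state a state from `init_train_state` (or a previous step).
#' @param class_batch list with `images` (`H x W x C x n`) and integer
#'   `labels`.
#' @param neural_batches named list (one per aligned block) with `X` images
#'   (`H x W x C x m`) and `Y` response rows (`m x S`), already paired.
#' @param spec an [alignment_spec()].
#' @param cfg a [train_config()].
#' @param step_seed integer seed for this step's dropout draws.
#' @return The updated state, with `last_loss` (a `loss_breakdown`)
#'   attached.
#' @export
training_step <- function(state, class_batch, neural_batches, spec, cfg,
                          step_seed = derive_seed(cfg$seed,
                                                  paste0("step", state$step))) {
  bb <- state$backbone
  fw <- backbone_forward(bb, class_batch$images, keep_cache = TRUE)
  sx <- softmax_xent(fw$logits, class_batch$labels, grad = TRUE)
  gb_total <- backbone_backward(bb, fw, dlogits = sx$dlogits)
  align_vals <- list()
  proj_grads <- list()
  with_seed(step_seed, {
    for (bn in aligned_blocks(spec)) {
      nb <- neural_batches[[bn]]
      if (is.null(nb)) {
        stop("training_step: no neural batch for aligned block ", bn)
      }
      lam <- spec$lambda_by_block[[bn]]
      nfw <- backbone_forward(bb, nb$X, upto = bn, keep_cache = TRUE)
      feats <- flatten_tap(nfw$taps[[bn]])
      pp <- state$projectors[[bn]]
      if (ncol(feats) != ncol(pp$f_x[[1]]$W)) {
        stop("training_step: feature width ", ncol(feats),
             " does not match projector input ", ncol(pp$f_x[[1]]$W),
             " for block ", bn)
      }
      if (ncol(nb$Y) != ncol(pp$f_y[[1]]$W)) {
        stop("training_step: response width ", ncol(nb$Y),
             " does not match brain-view projector input for block ", bn)
      }
      pv <- project_views(pp, feats, nb$Y, train = TRUE)
      al <- alignment_loss(pv$vp, spec, grad = TRUE)
      align_vals[[bn]] <- al$value
      bx <- mlp_backward(pp$f_x, pv$cache_x, lam * al$dZ)
      by <- mlp_backward(pp$f_y, pv$cache_y, lam * al$dZp)
      proj_grads[[bn]] <- projector_grads_tree(bx$grads, by$grads)
      gb_align <- backbone_backward(bb, nfw,
                                    dtaps = stats::setNames(list(bx$dX), bn))
      gb_total <- tree_add(gb_total, gb_align)
    }
  })
  st <- optim_step(state$opt_backbone, backbone_params(bb),
                   backbone_grads_tree(gb_total))
  state$opt_backbone <- st$opt
  state$backbone <- backbone_set_params(bb, st$params)
  for (bn in names(proj_grads)) {
    pu <- optim_step(state$opt_proj[[bn]],
                     projector_params(state$projectors[[bn]]),
                     proj_grads[[bn]])
    state$opt_proj[[bn]] <- pu$opt
    state$projectors[[bn]] <- projector_set_params(state$projectors[[bn]],
                                                   pu$params)
  }
  state$step <- state$step + 1L
  state$last_loss <- combined_loss(sx$value, align_vals, spec)
  state
}
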