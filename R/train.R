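# Full training runs: epoch loop over the classification data with neural
# minibatches cycling independently per aligned area, per-epoch metrics,
# best-validation checkpointing, and matched-seed experiment management.

# Random crop with zero padding + horizontal flip, per image. Draws come
# from the ambient RNG stream (callers seed it deterministically).
augment_batch <- function(images, pad = 4L) {
  d <- dim(images)
  H <- d[1]; W <- d[2]
  out <- images
  offs_h <- sample.int(2L * pad + 1L, d[4], replace = TRUE) - 1L
  offs_w <- sample.int(2L * pad + 1L, d[4], replace = TRUE) - 1L
  flips <- stats::runif(d[4]) < 0.5
  padded <- array(0, c(H + 2L * pad, W + 2L * pad, d[3], 1L))
  for (i in seq_len(d[4])) {
    padded[] <- 0
    padded[pad + seq_len(H), pad + seq_len(W), , 1L] <- images[, , , i]
    img <- padded[offs_h[i] + seq_len(H), offs_w[i] + seq_len(W), , 1L,
                  drop = FALSE]
    if (flips[i]) img <- img[, rev(seq_len(W)), , , drop = FALSE]
    out[, , , i] <- img
  }
  out
}

make_checkpoint <- function(state, cfg, spec, epoch, val_acc, config_id) {
  list(backbone = state$backbone, projectors = state$projectors,
       epoch = epoch, val_acc = val_acc, seed = cfg$seed,
       config_id = config_id, config_hash = config_hash(cfg, spec))
}

# Mean alignment loss per aligned block over the full neural set, eval mode
# (dropout off), batched at the neural batch size. Incomplete tail batches
# are dropped so every minibatch matches the training batch size.
evaluate_alignment <- function(backbone, projectors, neural_sets, spec, cfg) {
  out <- numeric(0)
  for (bn in aligned_blocks(spec)) {
    srs <- neural_sets[[bn]]
    pp <- projectors[[bn]]
    nb <- cfg$neural_batch
    nbatch <- srs$n %/% nb
    vals <- numeric(nbatch)
    for (k in seq_len(nbatch)) {
      idx <- ((k - 1L) * nb + 1L):(k * nb)
      feats <- extract_block_features(backbone, srs$stimuli[, , , idx,
                                                            drop = FALSE], bn)
      Y <- srs$responses[srs$pairing[idx], , drop = FALSE]
      pv <- project_views(pp, feats, Y, train = FALSE)
      vals[k] <- alignment_loss(pv$vp, spec)$value
    }
    out[bn] <- mean(vals)
  }
  out
}

#' Run one co-training experiment
#'
#' Iterates epochs over the classification data (optionally augmented),
#' interleaving one neural minibatch per aligned area per classification
#' step; each neural dataset cycles independently with reshuffling on every
#' pass. Records a per-epoch loss breakdown and validation accuracy, and
#' keeps the checkpoint with the highest validation accuracy (ties resolved
#' to the earliest epoch). Fully reproducible per seed.
#'
#' @param task labelled image task with `train`, `val`, `test` splits (each
#'   a list of `images` and `labels`), as produced by [generate_task()].
#' @param neural_sets named list of [stimulus_response_set()]s, keyed by
#'   area, covering every block with positive lambda.
#' @param spec an [alignment_spec()].
#' @param cfg a [train_config()].
#' @param config_id character label stored in checkpoints and metrics.
#' @param metrics_file optional path of an append-only per-epoch metrics CSV.
#' @param verbose print a structured log line per epoch.
#' @return An object of class `run_result`: `best` and `final` checkpoints,
#'   `metrics` data frame (epoch, ce, align_V1, align_V4, align_IT, total,
#'   val_acc), `final_alignment` (eval-mode per-block loss at the final
#'   epoch), plus the config objects.
#' @export
train_run <- function(task, neural_sets, spec, cfg, config_id = "run",
                      metrics_file = NULL, verbose = FALSE) {
  if (length(task$train$labels) == 0L) stop("train_run: empty training set")
  state <- init_train_state(cfg, spec, neural_sets)
  n_train <- length(task$train$labels)
  blocks <- aligned_blocks(spec)
  # independent cycling state per neural dataset
  ncycle <- lapply(blocks, function(bn) {
    list(order = integer(0), pos = 1L, pass = 0L)
  })
  names(ncycle) <- blocks
  next_neural <- function(bn) {
    st <- ncycle[[bn]]
    srs <- neural_sets[[bn]]
    nb <- cfg$neural_batch
    if (st$pos + nb - 1L > length(st$order)) {
      st$pass <- st$pass + 1L
      st$order <- with_seed(
        derive_seed(cfg$seed, paste0("neural_", bn, "_pass", st$pass)),
        sample.int(srs$n))
      st$pos <- 1L
    }
    idx <- st$order[st$pos:(st$pos + nb - 1L)]
    st$pos <- st$pos + nb
    ncycle[[bn]] <<- st
    list(X = srs$stimuli[, , , idx, drop = FALSE],
         Y = srs$responses[srs$pairing[idx], , drop = FALSE])
  }
  metrics <- list()
  best <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    order <- with_seed(derive_seed(cfg$seed, paste0("order_epoch", epoch)),
                       sample.int(n_train))
    ep_ce <- c(); ep_align <- list(); ep_total <- c()
    i <- 1L
    batch_i <- 0L
    while (i <= n_train) {
      j <- min(i + cfg$class_batch - 1L, n_train)
      idx <- order[i:j]
      imgs <- task$train$images[, , , idx, drop = FALSE]
      if (cfg$augment) {
        imgs <- with_seed(
          derive_seed(cfg$seed, paste0("aug_e", epoch, "_b", batch_i)),
          augment_batch(imgs))
      }
      nb <- lapply(stats::setNames(blocks, blocks), next_neural)
      state <- training_step(state,
                             list(images = imgs,
                                  labels = task$train$labels[idx]),
                             nb, spec, cfg)
      ep_ce <- c(ep_ce, state$last_loss$ce)
      ep_total <- c(ep_total, state$last_loss$total)
      for (bn in blocks) {
        ep_align[[bn]] <- c(ep_align[[bn]], state$last_loss$align[[bn]])
      }
      i <- j + 1L
      batch_i <- batch_i + 1L
    }
    val_pred <- predict_classes(state$backbone, task$val$images)
    val_acc <- mean(val_pred == task$val$labels)
    row <- data.frame(epoch = epoch, ce = mean(ep_ce),
                      align_V1 = mean(ep_align[["V1"]] %||% NA_real_),
                      align_V4 = mean(ep_align[["V4"]] %||% NA_real_),
                      align_IT = mean(ep_align[["IT"]] %||% NA_real_),
                      total = mean(ep_total), val_acc = val_acc)
    metrics[[epoch]] <- row
    if (!is.null(metrics_file)) {
      utils::write.table(row, metrics_file, sep = ",", row.names = FALSE,
                         col.names = !file.exists(metrics_file),
                         append = file.exists(metrics_file))
    }
    if (verbose) {
      message(sprintf("[%s] INFO epoch=%d ce=%.4f total=%.4f val_acc=%.4f",
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      epoch, row$ce, row$total, val_acc))
    }
    if (is.null(best) || val_acc > best$val_acc) {
      best <- make_checkpoint(state, cfg, spec, epoch, val_acc, config_id)
    }
  }
  final <- make_checkpoint(state, cfg, spec, cfg$epochs,
                           metrics[[cfg$epochs]]$val_acc, config_id)
  structure(
    list(best = best, final = final,
         metrics = do.call(rbind, metrics),
         final_alignment = evaluate_alignment(state$backbone,
                                              state$projectors,
                                              neural_sets, spec, cfg),
         spec = spec, cfg = cfg, config_id = config_id),
    class = "run_result")
}

#' Train every configuration once per seed (within-subjects design)
#'
#' For a given seed, every configuration starts from identical initial
#' weights and sees the identical sequence of classification minibatches
#' (initialization and data order are driven by seed-derived streams that
#' do not depend on the alignment configuration). Results are keyed
#' `(config, seed)` for paired testing.
#'
#' @param configs named list of [alignment_spec()]s (include the baseline
#'   as an all-zero-lambda spec).
#' @param seeds integer vector of at least 2 seeds.
#' @param base a [train_config()] whose seed field is overridden per run.
#' @param task,neural_sets as in [train_run()].
#' @param verbose forwarded to [train_run()].
#' @return Nested list `results[[config]][[as.character(seed)]]`, each a
#'   `run_result`.
#' @export
run_matched_seeds <- function(configs, seeds, base, task, neural_sets,
                              verbose = FALSE) {
  if (length(seeds) < 2L) stop("run_matched_seeds: need >= 2 seeds")
  if (is.null(names(configs)) || any(names(configs) == "")) {
    stop("run_matched_seeds: configs must be a named list")
  }
  results <- list()
  for (cname in names(configs)) {
    results[[cname]] <- list()
    for (s in seeds) {
      cfg <- base
      cfg$seed <- as.integer(s)
      results[[cname]][[as.character(s)]] <-
        train_run(task, neural_sets, configs[[cname]], cfg,
                  config_id = cname, verbose = verbose)
    }
  }
  results
}

#' Post-hoc alignability of a frozen backbone
#'
#' Measures how alignable a trained backbone's block representations are
#' without co-training: the backbone is frozen, fresh projector pairs are
#' trained with RMSprop on the alignment loss alone (block features are
#' precomputed once), and the final eval-mode per-block alignment loss is
#' returned. This is the reference the co-trained models are compared
#' against: co-training should leave representations that align better than
#' this post-hoc fit of a task-only backbone.
#'
#' @param backbone a trained (or untrained) [build_backbone()] result.
#' @param neural_sets named list of [stimulus_response_set()]s.
#' @param spec an [alignment_spec()] naming the blocks (positive lambda)
#'   and the loss.
#' @param cfg a [train_config()]; projector shape, optimizer settings,
#'   neural batch size and epoch count are taken from it.
#' @param steps number of projector update steps per block. Defaults to
#'   `epochs * (n / neural_batch)`.
#' @param train_dropout apply dropout while fitting the projectors
#'   (default `TRUE`, matching the conditions co-trained projectors are
#'   fitted under).
#' @return Named numeric vector of final per-block alignment losses.
#' @export
posthoc_alignment <- function(backbone, neural_sets, spec, cfg,
                              steps = NULL, train_dropout = TRUE) {
  out <- numeric(0)
  for (bn in aligned_blocks(spec)) {
    srs <- neural_sets[[bn]]
    feats <- extract_block_features(backbone, srs$stimuli, bn)
    Y <- srs$responses[srs$pairing, , drop = FALSE]
    pp <- build_projectors(ncol(feats), ncol(Y),
                           seed = derive_seed(cfg$seed,
                                              paste0("posthoc_", bn)),
                           width = cfg$projector_width,
                           out_dim = cfg$projector_out,
                           dropout = cfg$projector_dropout)
    opt <- rmsprop(lr = cfg$projector_lr, weight_decay = cfg$projector_wd)
    nb <- cfg$neural_batch
    pass <- 0L
    pos <- 1L
    order <- integer(0)
    nsteps <- if (is.null(steps)) cfg$epochs * max(1L, srs$n %/% nb) else steps
    for (step in seq_len(nsteps)) {
      if (pos + nb - 1L > length(order)) {
        pass <- pass + 1L
        order <- with_seed(
          derive_seed(cfg$seed, paste0("posthoc_", bn, "_pass", pass)),
          sample.int(srs$n))
        pos <- 1L
      }
      idx <- order[pos:(pos + nb - 1L)]
      pos <- pos + nb
      pv <- with_seed(
        derive_seed(cfg$seed, paste0("posthoc_", bn, "_drop", step)),
        project_views(pp, feats[idx, , drop = FALSE],
                      Y[idx, , drop = FALSE], train = train_dropout))
      al <- alignment_loss(pv$vp, spec, grad = TRUE)
      bx <- mlp_backward(pp$f_x, pv$cache_x, al$dZ)
      by <- mlp_backward(pp$f_y, pv$cache_y, al$dZp)
      pu <- optim_step(opt, projector_params(pp),
                       projector_grads_tree(bx$grads, by$grads))
      opt <- pu$opt
      pp <- projector_set_params(pp, pu$params)
    }
    nbatch <- srs$n %/% nb
    vals <- numeric(nbatch)
    for (k in seq_len(nbatch)) {
      idx <- ((k - 1L) * nb + 1L):(k * nb)
      pv <- project_views(pp, feats[idx, , drop = FALSE],
                          Y[idx, , drop = FALSE], train = FALSE)
      vals[k] <- alignment_loss(pv$vp, spec)$value
    }
    out[bn] <- mean(vals)
  }
  out
}
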