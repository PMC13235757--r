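# Synthetic data: a desk-scale classification task with a parametric class
# signal, teacher-derived stimulus-response sets emulating V1/V4/IT
# recordings, and four parametric image corruptions at five severities.
# Everything is bit-reproducible from (spec, seed).

#' Synthetic classification task specification
#'
#' Each class is an oriented grating (class-dependent orientation and
#' spatial phase family) tinted with a class-dependent colour, plus i.i.d.
#' Gaussian pixel noise. The signal is linear enough in pixel space for a
#' logistic-regression oracle to beat chance comfortably while leaving the
#' network something to learn.
#'
#' @param num_classes number of balanced classes (default 8).
#' @param images_per_class images per class (default 250).
#' @param image_size image side length in pixels (default 32).
#' @param noise_sd pixel-noise standard deviation (default 0.15).
#' @param seed generation seed.
#' @return An object of class `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(num_classes = 8L, images_per_class = 250L,
                                image_size = 32L, noise_sd = 0.15,
                                seed = 1L) {
  if (image_size < 8L) {
    stop("synthetic_task_spec: image_size must be >= 8 for the grating ",
         "signal family")
  }
  structure(list(num_classes = as.integer(num_classes),
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_task_spec")
}

grating_image <- function(size, theta, phase, freq, tint) {
  g <- expand.grid(h = seq_len(size), w = seq_len(size))
  wave <- 0.5 + 0.5 * sin(freq * (g$h * cos(theta) + g$w * sin(theta)) + phase)
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(wave * tint[ch], size, size)
  img
}

#' Generate a balanced synthetic classification task
#'
#' Deterministic per seed; classes are exactly balanced; images are in
#' `[0, 1]` before normalization. Splits into train/val/test (80/10/10 by
#' default) and attaches channel normalization statistics computed on the
#' training split; `images` in the returned splits are already normalized,
#' raw images are kept under `raw` for corruption pipelines.
#'
#' @param spec a [synthetic_task_spec()].
#' @return A list with `train`, `val`, `test` (each `images`, `labels`,
#'   `raw`), `norm_stats` (`mean`, `sd` per channel) and `spec`.
#' @export
generate_task <- function(spec = synthetic_task_spec()) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  K <- spec$num_classes
  n <- K * spec$images_per_class
  size <- spec$image_size
  with_seed(derive_seed(spec$seed, "task"), {
    labels <- rep(seq_len(K), each = spec$images_per_class)
    images <- array(0, c(size, size, 3L, n))
    tints <- cbind(0.4 + 0.6 * cos(seq_len(K))^2,
                   0.4 + 0.6 * sin(seq_len(K))^2,
                   0.4 + 0.6 * cos(seq_len(K) + 1)^2)
    for (i in seq_len(n)) {
      k <- labels[i]
      img <- grating_image(size,
                           theta = (k - 1) * pi / K,
                           phase = stats::runif(1, 0, 2 * pi),
                           freq = 2 * pi * (2 + (k %% 3)) / size,
                           tint = tints[k, ])
      img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd),
                         dim(img))
      img[img < 0] <- 0; img[img > 1] <- 1
      images[, , , i] <- img
    }
    perm <- sample.int(n)
    images <- images[, , , perm, drop = FALSE]
    labels <- labels[perm]
    n_val <- round(0.1 * n)
    n_test <- round(0.1 * n)
    idx_val <- seq_len(n_val)
    idx_test <- n_val + seq_len(n_test)
    idx_train <- (n_val + n_test + 1L):n
    stats_mean <- numeric(3); stats_sd <- numeric(3)
    for (ch in 1:3) {
      v <- images[, , ch, idx_train]
      stats_mean[ch] <- mean(v)
      stats_sd[ch] <- stats::sd(as.vector(v))
    }
    norm <- list(mean = stats_mean, sd = stats_sd)
    split <- function(idx) {
      raw <- images[, , , idx, drop = FALSE]
      list(images = normalize_images(raw, norm), labels = labels[idx],
           raw = raw)
    }
    list(train = split(idx_train), val = split(idx_val),
         test = split(idx_test), norm_stats = norm, spec = spec)
  })
}

#' Normalize images with per-channel statistics
#'
#' @param images array `H x W x C x N` in `[0, 1]`.
#' @param norm_stats list with `mean` and `sd` per channel.
#' @return Normalized array of the same shape.
#' @export
normalize_images <- function(images, norm_stats) {
  out <- images
  for (ch in seq_along(norm_stats$mean)) {
    out[, , ch, ] <- (images[, , ch, ] - norm_stats$mean[ch]) /
      norm_stats$sd[ch]
  }
  out
}

#' Teacher specification for synthetic neural responses
#'
#' The teacher is a frozen, randomly initialized backbone of the same
#' architecture family as the trainee. Per-area responses are a fixed
#' random linear readout of the teacher's matching block features followed
#' by rectification, plus Gaussian noise — so each area's responses carry
#' stimulus-dependent structure at the right depth of abstraction. Default
#' site counts emulate the recording set sizes (V1 166, V4 88, IT 168).
#'
#' @param variant teacher backbone variant.
#' @param input_size stimulus side length.
#' @param site_counts named site counts per area.
#' @param response_noise_sd Gaussian response noise (0 = deterministic).
#' @param seed teacher + readout seed (the teacher is never trained).
#' @return An object of class `teacher_spec`.
#' @export
teacher_spec <- function(variant = "tiny", input_size = 32L,
                         site_counts = c(V1 = 166L, V4 = 88L, IT = 168L),
                         response_noise_sd = 0, seed = 1L) {
  structure(list(variant = variant, input_size = as.integer(input_size),
                 site_counts = site_counts,
                 response_noise_sd = response_noise_sd,
                 seed = as.integer(seed)),
            class = "teacher_spec")
}

#' Generate teacher-derived neural responses for a stimulus set
#'
#' @param stimuli array `H x W x C x N` of (normalized) stimulus images.
#' @param teacher a [teacher_spec()].
#' @param area one of `"V1"`, `"V4"`, `"IT"`.
#' @return A [stimulus_response_set()] with identity pairing.
#' @export
generate_responses <- function(stimuli, teacher, area) {
  stopifnot(inherits(teacher, "teacher_spec"))
  if (!area %in% ALIGN_BLOCKS) {
    stop("generate_responses: unknown area '", area, "'")
  }
  bspec <- backbone_spec(teacher$variant, num_classes = 2L,
                         input_size = teacher$input_size)
  bb <- build_backbone(bspec, derive_seed(teacher$seed, "teacher"))
  feats <- extract_block_features(bb, stimuli, area)
  S <- teacher$site_counts[[area]]
  with_seed(derive_seed(teacher$seed, paste0("readout_", area)), {
    W <- matrix(stats::rnorm(ncol(feats) * S, sd = 1 / sqrt(ncol(feats))),
                ncol(feats), S)
    b <- stats::rnorm(S, sd = 0.1)
    resp <- pmax(feats %*% W + rep(b, each = nrow(feats)), 0)
    if (teacher$response_noise_sd > 0) {
      resp <- resp + matrix(stats::rnorm(length(resp),
                                         sd = teacher$response_noise_sd),
                            nrow(resp), ncol(resp))
    }
    stimulus_response_set(stimuli, resp, area)
  })
}

CORRUPTION_KINDS <- c("gaussian_noise", "contrast", "brightness", "pixelate")

# severity parameter tables, monotone in severity (1 mildest .. 5 harshest)
CORRUPTION_PARAMS <- list(
  gaussian_noise = c(0.04, 0.08, 0.12, 0.18, 0.26),   # noise sd
  contrast = c(0.75, 0.6, 0.45, 0.3, 0.15),           # contrast factor
  brightness = c(0.08, 0.16, 0.24, 0.32, 0.40),       # additive shift
  pixelate = c(0.8, 0.6, 0.4, 0.3, 0.2)               # downsample fraction
)

#' Apply a parametric corruption at a given severity
#'
#' Four corruption families, one per CIFAR-C category exercised here:
#' additive Gaussian noise (stochastic, deterministic per seed), contrast
#' reduction towards the per-image mean, additive brightness, and pixelate
#' (nearest-neighbour down/up-sampling). Pixel range is preserved by
#' clipping to `[0, 1]`. Operates on raw (unnormalized) images.
#'
#' @param images array `H x W x C x N` in `[0, 1]`.
#' @param kind one of `r paste(CORRUPTION_KINDS, collapse = ", ")`.
#' @param severity integer 1 (mildest) to 5 (harshest).
#' @param seed seed for stochastic kinds (ignored by deterministic ones).
#' @return Corrupted copy of `images`.
#' @export
corrupt_images <- function(images, kind, severity, seed = 1L) {
  if (!kind %in% CORRUPTION_KINDS) {
    stop("corrupt_images: unknown corruption kind '", kind, "'")
  }
  if (!severity %in% 1:5) stop("corrupt_images: severity must be in 1..5")
  par <- CORRUPTION_PARAMS[[kind]][severity]
  out <- switch(kind,
    gaussian_noise = with_seed(
      derive_seed(seed, paste0("gn", severity)),
      images + array(stats::rnorm(length(images), sd = par), dim(images))),
    contrast = {
      d <- dim(images)
      o <- images
      for (i in seq_len(d[4])) {
        m <- mean(images[, , , i])
        o[, , , i] <- (images[, , , i] - m) * par + m
      }
      o
    },
    brightness = images + par,
    pixelate = {
      # average within coarse cells, then upsample the cell value
      d <- dim(images)
      small <- max(2L, round(d[1] * par))
      cell <- floor((seq_len(d[1]) - 1L) * small / d[1]) + 1L  # pixel -> cell
      A <- matrix(0, small, d[1])                              # cell averager
      A[cbind(cell, seq_len(d[1]))] <- 1
      A <- A / rowSums(A)
      o <- images
      for (i in seq_len(d[4])) {
        for (ch in seq_len(d[3])) {
          coarse <- A %*% images[, , ch, i] %*% t(A)
          o[, , ch, i] <- coarse[cell, cell]
        }
      }
      o
    })
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Build the full corrupted evaluation suite for a test split
#'
#' @param raw_images raw `[0, 1]` test images.
#' @param labels matching labels.
#' @param norm_stats normalization statistics of the clean training set
#'   (corrupted images are normalized with the clean statistics).
#' @param kinds corruption kinds to include.
#' @param seed seed for stochastic corruptions.
#' @return Named list `sets[[kind]][[severity]]` of labelled image sets.
#' @export
corruption_suite <- function(raw_images, labels, norm_stats,
                             kinds = CORRUPTION_KINDS, seed = 1L) {
  out <- list()
  for (kind in kinds) {
    out[[kind]] <- lapply(1:5, function(sv) {
      list(images = normalize_images(
             corrupt_images(raw_images, kind, sv, seed = seed), norm_stats),
           labels = labels)
    })
  }
  out
}
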