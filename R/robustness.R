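# Robustness evaluation: per-(corruption, severity) accuracies, severity
# averaging, relative gain against a baseline, and matched-seed paired
# t-tests with Benjamini-Hochberg FDR correction.

#' Build a robustness table from per-condition accuracies
#'
#' @param accuracies data frame with columns `corruption`, `severity`
#'   (integers 1..5) and `accuracy` (in `[0, 1]`).
#' @param clean_accuracy scalar clean-test accuracy.
#' @param seed integer seed of the run the table describes.
#' @param config_id character label of the training configuration.
#' @return An object of class `robustness_table`.
#' @export
robustness_table <- function(accuracies, clean_accuracy, seed, config_id) {
  stopifnot(is.data.frame(accuracies),
            all(c("corruption", "severity", "accuracy") %in% names(accuracies)))
  if (any(accuracies$accuracy < 0 | accuracies$accuracy > 1)) {
    stop("robustness_table: accuracies must lie in [0, 1]")
  }
  for (corr in unique(accuracies$corruption)) {
    sv <- sort(accuracies$severity[accuracies$corruption == corr])
    if (!identical(as.integer(sv), 1:5)) {
      stop("robustness_table: corruption '", corr,
           "' must have severities exactly 1..5 (got ",
           paste(sv, collapse = ","), ")")
    }
  }
  structure(list(accuracies = accuracies, clean_accuracy = clean_accuracy,
                 seed = as.integer(seed), config_id = config_id),
            class = "robustness_table")
}

#' Top-1 accuracy of a checkpoint on clean and corrupted test sets
#'
#' Runs the backbone in eval mode over every `(corruption, severity)` image
#' set and records top-1 accuracy, plus clean-test accuracy.
#'
#' @param checkpoint a checkpoint list as produced by [train_run()] (or
#'   loaded with [load_checkpoint()]), holding the backbone.
#' @param corrupted named list: `corrupted[[corruption]][[severity]]` is a
#'   labelled image set (list with `images` array `H x W x C x N` and
#'   integer `labels`), severities 1..5.
#' @param clean labelled image set used for the clean accuracy.
#' @param batch_size evaluation minibatch size.
#' @return A [robustness_table()].
#' @export
corruption_accuracy <- function(checkpoint, corrupted, clean,
                                batch_size = 256L) {
  bb <- checkpoint$backbone
  acc_of <- function(set) {
    n_img <- dim(set$images)[4]
    if (length(set$labels) != n_img) {
      stop("corruption_accuracy: image/label count mismatch (",
           n_img, " images vs ", length(set$labels), " labels)")
    }
    pred <- predict_classes(bb, set$images, batch_size = batch_size)
    mean(pred == set$labels)
  }
  rows <- list()
  for (corr in names(corrupted)) {
    sets <- corrupted[[corr]]
    if (length(sets) != 5L) {
      stop("corruption_accuracy: corruption '", corr,
           "' must provide severities 1..5")
    }
    for (sv in 1:5) {
      rows[[length(rows) + 1L]] <- data.frame(
        corruption = corr, severity = sv, accuracy = acc_of(sets[[sv]]))
    }
  }
  robustness_table(do.call(rbind, rows),
                   clean_accuracy = acc_of(clean),
                   seed = checkpoint$seed %||% NA_integer_,
                   config_id = checkpoint$config_id %||% "unknown")
}

#' Severity-averaged accuracy per corruption
#'
#' Unweighted mean of the five severity accuracies for each corruption.
#'
#' @param table a [robustness_table()].
#' @return Named numeric vector, one severity-averaged accuracy per
#'   corruption.
#' @export
severity_average <- function(table) {
  stopifnot(inherits(table, "robustness_table"))
  acc <- table$accuracies
  out <- tapply(acc$accuracy, acc$corruption, function(a) {
    if (length(a) != 5L) stop("severity_average: missing severity levels")
    mean(a)
  })
  stats::setNames(as.numeric(out), names(out))
}

#' Relative robustness gain over a baseline
#'
#' `(model / baseline) * 100`; values above 100 indicate improved
#' robustness relative to the baseline model.
#'
#' @param model_avg severity-averaged accuracy of the model.
#' @param baseline_avg severity-averaged accuracy of the baseline; must be
#'   positive.
#' @return Percentage gain (vectorized over matching inputs).
#' @export
relative_gain <- function(model_avg, baseline_avg) {
  if (any(baseline_avg <= 0)) {
    stop("relative_gain: baseline average must be > 0 (normalization ",
         "undefined at 0)")
  }
  100 * model_avg / baseline_avg
}

#' Paired t-test on matched per-seed scores
#'
#' Two-sided paired t-test on the seed-wise differences `x - y`;
#' `df = n - 1`. Zero-variance differences with a non-zero mean are
#' reported explicitly as an infinite t with p = 0; identical samples give
#' t = 0, p = 1.
#'
#' @param x,y numeric vectors of per-seed scores, matched by position
#'   (same seed ordering), length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired_ttest: unequal lengths")
  if (length(x) < 2L) stop("paired_ttest: need at least 2 matched pairs")
  d <- x - y
  if (all(d == d[1])) {
    if (d[1] == 0) {
      return(list(t = 0, df = length(d) - 1L, p = 1))
    }
    warning("paired_ttest: zero-variance non-zero differences; ",
            "reporting infinite t and p = 0")
    return(list(t = sign(d[1]) * Inf, df = length(d) - 1L, p = 0))
  }
  ht <- tryCatch(stats::t.test(x, y, paired = TRUE), error = function(e) NULL)
  if (is.null(ht)) {
    # differences constant up to floating-point jitter
    warning("paired_ttest: essentially constant non-zero differences; ",
            "reporting infinite t and p = 0")
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0))
  }
  list(t = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
       p = ht$p.value)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Standard step-up procedure: adjusted p-values are monotone, capped at 1,
#' and a hypothesis is rejected when its adjusted p is at most `q`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q FDR threshold (default 0.05).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("bh_fdr: p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Matched-seed robustness report for one model against a baseline
#'
#' For every corruption, collects the seed-wise severity-averaged scores of
#' the model and of the baseline, runs a paired t-test on the matched
#' differences, corrects the family of all corruptions with
#' Benjamini-Hochberg at threshold `q`, and reports the mean relative gain
#' with its standard error across seeds (baseline normalization per
#' matched seed).
#'
#' @param grid named list of [robustness_table()]s; names are
#'   `"<config_id>:<seed>"` or the tables carry `config_id`/`seed` fields
#'   (the latter are used).
#' @param baseline_id `config_id` of the baseline configuration.
#' @param model_id `config_id` of the model to compare (default: the
#'   unique non-baseline id).
#' @param q FDR threshold (default 0.05).
#' @return An object of class `stat_report`: data frame `per_corruption`
#'   with columns `corruption`, `t`, `df`, `p`, `p_fdr`, `significant`,
#'   `mean_gain`, `sem_gain`, plus `grand_mean_gain` (mean over corruptions
#'   of the per-seed grand mean gain) and metadata.
#' @export
experiment_report <- function(grid, baseline_id, model_id = NULL, q = 0.05) {
  ids <- vapply(grid, function(g) g$config_id, character(1))
  seeds <- vapply(grid, function(g) g$seed, integer(1))
  if (is.null(model_id)) {
    model_id <- setdiff(unique(ids), baseline_id)
    if (length(model_id) != 1L) {
      stop("experiment_report: specify model_id (found: ",
           paste(unique(ids), collapse = ", "), ")")
    }
  }
  sseq <- sort(unique(seeds))
  pick <- function(id, s) {
    k <- which(ids == id & seeds == s)
    if (length(k) != 1L) {
      stop("experiment_report: incomplete grid, missing or duplicated cell (",
           id, ", seed ", s, ")")
    }
    grid[[k]]
  }
  model_avg <- sapply(sseq, function(s) severity_average(pick(model_id, s)))
  base_avg <- sapply(sseq, function(s) severity_average(pick(baseline_id, s)))
  corrs <- rownames(model_avg)
  tests <- lapply(corrs, function(cn) {
    paired_ttest(model_avg[cn, ], base_avg[cn, ])
  })
  p <- vapply(tests, function(tt) tt$p, numeric(1))
  fdr <- bh_fdr(p, q = q)
  gains <- relative_gain(model_avg, base_avg)  # corruption x seed, per seed
  per <- data.frame(
    corruption = corrs,
    t = vapply(tests, function(tt) tt$t, numeric(1)),
    df = vapply(tests, function(tt) tt$df, numeric(1)),
    p = p,
    p_fdr = fdr$p_adjusted,
    significant = fdr$reject,
    mean_gain = rowMeans(gains),
    sem_gain = apply(gains, 1L, stats::sd) / sqrt(length(sseq)),
    row.names = NULL
  )
  grand_per_seed <- relative_gain(colMeans(model_avg), colMeans(base_avg))
  structure(
    list(per_corruption = per,
         grand_mean_gain = mean(grand_per_seed),
         grand_sem_gain = stats::sd(grand_per_seed) / sqrt(length(sseq)),
         grand_test = paired_ttest(colMeans(model_avg), colMeans(base_avg)),
         model_id = model_id, baseline_id = baseline_id,
         seeds = sseq, q = q,
         error_bars = "standard error of per-seed relative gains"),
    class = "stat_report"
  )
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report> ", x$model_id, " vs ", x$baseline_id,
      " over seeds ", paste(x$seeds, collapse = ","), "\n", sep = "")
  print(x$per_corruption, digits = 4)
  cat(sprintf("grand mean gain %.2f%% (sem %.2f)\n",
              x$grand_mean_gain, x$grand_sem_gain))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
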