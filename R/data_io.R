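# On-disk interchange: stimulus-response sets as a directory of PNG files
# plus a responses.csv keyed by filename, run configs as YAML with a
# content hash, checkpoints as native serialized R containers, and tidy
# CSV/JSON outputs for the robustness reports.

config_hash <- function(cfg, spec) {
  txt <- paste(utils::capture.output(utils::str(cfg)),
               utils::capture.output(utils::str(spec)), collapse = "\n")
  h <- 0
  for (c in utf8ToInt(txt)) h <- (h * 31 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a stimulus-response set as PNG files + responses.csv
#'
#' One PNG per stimulus (`stim_000001.png`, ...) and a `responses.csv`
#' whose first column `filename` keys the response rows; remaining columns
#' are sites. An `area.txt` file records the area tag and the pairing
#' permutation.
#'
#' @param srs a [stimulus_response_set()] (images expected in `[0, 1]`).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_srs_dir <- function(srs, dir) {
  stopifnot(inherits(srs, "stimulus_response_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fnames <- sprintf("stim_%06d.png", seq_len(srs$n))
  for (i in seq_len(srs$n)) {
    img <- srs$stimuli[, , , i]
    img[img < 0] <- 0; img[img > 1] <- 1
    png::writePNG(img, file.path(dir, fnames[i]))
  }
  resp <- data.frame(filename = fnames, srs$responses, check.names = FALSE)
  names(resp) <- c("filename", sprintf("site_%04d", seq_len(srs$sites)))
  utils::write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE)
  writeLines(c(paste0("area: ", srs$area),
               paste0("pairing: ", paste(srs$pairing, collapse = " "))),
             file.path(dir, "area.txt"))
  invisible(dir)
}

#' Read a stimulus-response set written by [write_srs_dir()]
#'
#' @param dir directory containing the PNG files, `responses.csv` and
#'   `area.txt`.
#' @return A [stimulus_response_set()].
#' @export
read_srs_dir <- function(dir) {
  resp <- utils::read.csv(file.path(dir, "responses.csv"),
                          check.names = FALSE)
  fnames <- resp$filename
  responses <- as.matrix(resp[, -1L, drop = FALSE])
  first <- png::readPNG(file.path(dir, fnames[1]))
  if (length(dim(first)) == 2L) dim(first) <- c(dim(first), 1L)
  d <- dim(first)
  stimuli <- array(0, c(d[1], d[2], d[3], length(fnames)))
  for (i in seq_along(fnames)) {
    img <- png::readPNG(file.path(dir, fnames[i]))
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    stimuli[, , , i] <- img[, , seq_len(d[3])]
  }
  meta <- readLines(file.path(dir, "area.txt"))
  area <- sub("^area: ", "", meta[1])
  pairing <- as.integer(strsplit(sub("^pairing: ", "", meta[2]), " ")[[1]])
  stimulus_response_set(stimuli, responses, area, pairing = pairing)
}

#' Write a run configuration (train config + alignment spec) to YAML
#'
#' The document carries a content hash so the exact configuration of every
#' run can be verified later.
#'
#' @param cfg a [train_config()].
#' @param spec an [alignment_spec()].
#' @param path output YAML file.
#' @return The hash string, invisibly.
#' @export
write_run_config <- function(cfg, spec, path) {
  doc <- list(
    train = unclass(cfg),
    alignment = list(lambda_by_block = as.list(spec$lambda_by_block),
                     loss_kind = spec$loss_kind,
                     loss_params = unclass(spec$loss_params)),
    hash = config_hash(cfg, spec))
  yaml::write_yaml(doc, path)
  invisible(doc$hash)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path YAML file.
#' @return List with `cfg` ([train_config()]) and `spec`
#'   ([alignment_spec()]).
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  tr <- doc$train
  cfg <- do.call(train_config, tr[intersect(names(tr),
                                            names(formals(train_config)))])
  lp <- doc$alignment$loss_params
  params <- switch(doc$alignment$loss_kind,
    dcca = dcca_params(lp$C, lp$rx, lp$ry),
    infonce = infonce_params(lp$tau),
    vicreg = vicreg_params(lp$alpha, lp$mu, lp$nu, lp$gamma, lp$eps,
                           lp$variance_hinge))
  spec <- alignment_spec(unlist(doc$alignment$lambda_by_block),
                         doc$alignment$loss_kind, params)
  list(cfg = cfg, spec = spec)
}

#' Save / load a training checkpoint
#'
#' Checkpoints are single-file native serialized containers holding the
#' backbone parameters, projector parameters, config hash, seed and epoch.
#'
#' @param checkpoint a checkpoint list (e.g. `run_result$best`).
#' @param path file path (`.rds`).
#' @return `path` invisibly (save); the checkpoint list (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Tidy accuracy table across a results grid
#'
#' @param grid list of [robustness_table()]s.
#' @return Data frame with columns corruption, severity, config, seed,
#'   accuracy.
#' @export
tidy_accuracies <- function(grid) {
  do.call(rbind, lapply(grid, function(tb) {
    cbind(tb$accuracies, config = tb$config_id, seed = tb$seed)
  }))
}

#' Write a stat report to JSON
#'
#' @param report a `stat_report` from [experiment_report()].
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(model = report$model_id, baseline = report$baseline_id,
         seeds = report$seeds, q = report$q,
         error_bars = report$error_bars,
         per_corruption = report$per_corruption,
         grand_mean_gain = report$grand_mean_gain,
         grand_sem_gain = report$grand_sem_gain),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
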