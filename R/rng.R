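#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' One master seed controls every stochastic component of a run (weight
#' initialization, data ordering, augmentation, dropout, response noise).
#' Components draw from independent streams obtained by hashing the master
#' seed together with a short tag, so adding or removing one consumer (for
#' example, the projectors that a baseline run does not have) never shifts
#' the draws of another. The hash is a 31-bit multiplicative mix, so derived
#' seeds always fit a signed 32-bit integer.
#'
#' @param seed integer master seed.
#' @param tag character scalar naming the stream (e.g. `"shuffle_epoch3"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, length(tag) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (c in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + c) %% m
  }
  h <- (h * 2654435761) %% m
  as.integer(h %% (m - 1L) + 1L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
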