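## Small shared helpers: seeding and logging.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG
# state afterwards (local reproducibility without global side effects).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Derive a per-stage seed from a global seed
#'
#' Hashes the stage name into an offset so that each pipeline stage gets
#' an independent, reproducible RNG stream from one global seed. Result is
#' kept within the 32-bit integer range R requires.
#'
#' @param global_seed integer global seed.
#' @param stage stage name (character).
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647L)
}
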