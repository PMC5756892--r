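#' Run code with a local RNG seed
#'
#' Evaluates `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so simulation helpers do not clobber the caller's
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Mixes a master seed with a stage name so that every pipeline stage gets a
#' reproducible substream that does not depend on the order stages run in.
#' The result is always a non-negative value below 2^31 - 1.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label (e.g. `"nri"`, `"subset_17"`).
#' @return An integer seed.
#' @export
#' @examples
#' stage_seed(42, "nri")
stage_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer((abs(as.numeric(master_seed)) %% m * 48271 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
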