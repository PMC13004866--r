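#' @keywords internal
"_PACKAGE"

## Frame rate used throughout: two-photon acquisition at 30 Hz.
FRAME_RATE <- 30

## Task timing constants (seconds): 1 s stimulus, 0.5 s trace interval,
## reward 1.5 s after stimulus onset on CS+ trials only.
STIM_DUR_S <- 1.0
TRACE_DUR_S <- 0.5
REWARD_DELAY_S <- STIM_DUR_S + TRACE_DUR_S

#' Evaluate code with a local, restorable RNG state
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' `.Random.seed` on exit, so generator calls do not perturb the session
#' RNG stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive n reproducible sub-seeds from one master seed, so independent
## generator components (e.g. behaviour vs imaging noise) draw from
## separate streams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
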