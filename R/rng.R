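#' Named reproducible RNG streams
#'
#' The simulation draws from separate named streams (monocyte spawning,
#' differentiation, movement, vessel remodeling) so that, under the same
#' seed, the draw sequence of one concern is unaffected by how often the
#' others draw. Streams are derived deterministically from a single seed
#' and hold independent Mersenne-Twister states.
#'
#' @param seed Integer seed.
#' @param names Stream names.
#' @return An environment mapping names to saved RNG states.
#' @export
make_streams <- function(seed,
                         names = c("spawn", "diff", "move", "vessel")) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  subs <- sample.int(.Machine$integer.max - 1L, length(names))
  e <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(subs[i])
    e[[names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  e
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Evaluate an expression under a named RNG stream
#'
#' Swaps the stream's state into the global RNG, evaluates `expr`, saves
#' the advanced state back into the stream, and restores the caller's RNG.
#'
#' @param streams Environment from [make_streams()].
#' @param name Stream name.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", streams[[name]], envir = globalenv())
  on.exit({
    streams[[name]] <- get(".Random.seed", envir = globalenv())
    restore_rng(old)
  })
  expr
}
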