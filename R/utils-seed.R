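# Seed plumbing: every stochastic stage draws from its own seed derived from
# the run seed, so adding a stage never perturbs earlier draws, and no helper
# disturbs the caller's RNG stream.

#' Derive a stage seed from a run seed
#'
#' Deterministic 32-bit mix of a run seed and a stage index; distinct stages
#' get well-separated streams.
#'
#' @param seed integer run seed.
#' @param stage integer stage index.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stage) * 104729
  as.integer(s %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
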