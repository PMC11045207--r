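#' Evaluate code under a temporary RNG seed
#'
#' Sets the R RNG to `seed`, evaluates `code` in the caller's frame and
#' restores the previous RNG state afterwards, so package internals
#' never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a stage seed from a top-level pipeline seed
#'
#' Every pipeline stage consumes randomness through a seed derived
#' deterministically from the single top-level seed, so any stage can be
#' replayed in isolation. The derivation is `(seed * 101 + offset)`
#' folded into the 32-bit signed integer range.
#'
#' @param seed top-level integer seed.
#' @param offset small integer identifying the stage.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% 2147483647)
}
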