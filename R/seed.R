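#' Derive a reproducible substream seed from a global seed and a label
#'
#' All pipeline stages draw their randomness from substreams derived from one
#' global seed, so that toggling a stage on or off never shifts the draws of
#' another stage. The derivation hashes the (seed, label) pair and folds the
#' result into a 31-bit integer suitable for [set.seed()].
#'
#' @param seed integer global seed.
#' @param label character stage label (e.g. `"synth:subject3"`).
#' @return an integer in `[0, 2^31)`.
#' @examples
#' seed_stream(1, "synth:subject1")
#' @export
seed_stream <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

# Run code under a local RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
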