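#' Seed substreams
#'
#' One user-facing seed feeds a named substream per randomized stage, so
#' adding or reordering a stage never perturbs the draws of another.
#' Implemented by hashing (seed, stream name) into a sub-seed and
#' restoring the caller's RNG state afterwards.
#'
#' @keywords internal
#' @noRd
.subseed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 100003 + h) %% 2147483647)
}

# evaluate `code` under a named RNG substream, restoring caller state
with_substream <- function(seed, name, code) {
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
  set.seed(.subseed(seed, name))
  force(code)
}
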