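#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' Every stochastic generator in the package draws from its own named
#' substream, so adding a new generator (or reordering calls) never perturbs
#' the draws of an existing one. The sub-seed is a deterministic hash of the
#' master seed and the stream name, kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param name Character stream name, e.g. `"mrio"` or `"species"`.
#' @return An integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(name), length(name) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  # both factors < 2^31 so the product stays exactly representable as a double
  as.integer((h + (abs(seed) %% 2147480009) * 7919) %% 2147483629L)
}

#' Evaluate code under a named RNG substream, restoring the RNG state after
#'
#' @param seed Master seed.
#' @param name Substream name.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_substream <- function(seed, name, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}
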