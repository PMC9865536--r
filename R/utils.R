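## shared internal helpers

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (ensemble
#' decompositions, ICA restarts, weight initialisation) do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

## derive a child seed (< 2^31) from a base seed and a stream index
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629L)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

## cache environment for expensive design objects (FIR filters, DPSS tapers)
.anescore_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!is.null(.anescore_cache[[key]])) return(.anescore_cache[[key]])
  val <- builder()
  assign(key, val, envir = .anescore_cache)
  val
}
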