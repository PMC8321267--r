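#' Derive a reproducible sub-seed from a root seed and a label
#'
#' All randomness in the package flows from a single root seed through named
#' substreams, so that multi-stage experiments (generate, translate, segment)
#' are reproducible end to end while stages stay statistically decoupled.
#'
#' @param seed integer root seed.
#' @param label character stream name (e.g. `"cyclegan"`, `"augment-epoch-3"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  # simple polynomial rolling hash, kept inside 2^31 via repeated modulo
  h <- 0
  for (ch in codes) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 7919 + h + 17) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never perturbs
#' the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
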