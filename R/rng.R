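#' Derive a per-operation RNG seed from a master seed
#'
#' Every stochastic operation in the package draws from its own RNG stream,
#' seeded deterministically from a master seed plus the operation name. This
#' gives stage-level reproducibility: re-running one stage with the same
#' master seed reproduces its draws regardless of what ran before it.
#'
#' @param seed master seed (integer-like).
#' @param op operation name, e.g. `"simulate_track"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
op_seed <- function(seed, op) {
  stopifnot(is.character(op), length(op) == 1L, is.finite(seed))
  codes <- utf8ToInt(op)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000000007
  as.integer((abs(as.numeric(seed)) %% 1048573) * 2039 + h %% 1048573) %% 2147483647L
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
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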