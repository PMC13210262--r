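#' Derive a reproducible child seed
#'
#' All randomness in a study flows from one master seed. Per-replicate child
#' seeds are derived deterministically so any single replicate can be rerun in
#' isolation (and replicates can be executed in any order or in parallel
#' without sharing RNG state).
#'
#' The derivation is an integer hash: starting from the master seed, each
#' component of `key` (a character scenario identifier is folded byte-wise,
#' integers directly) is mixed in with the multiplicative congruential update
#' `state <- (state * 48271 + component) mod (2^31 - 1)`, the Lehmer/MINSTD
#' multiplier. The result is always in `[1, 2^31 - 2]` and therefore a valid
#' `set.seed()` argument on every platform.
#'
#' @param master_seed integer master seed.
#' @param ... further key components: integers (e.g. replicate index) or
#'   character scalars (e.g. a scenario id), hashed in order.
#' @return a single integer seed.
#' @examples
#' child_seed(42, "n60-2to17", 7L)
#' @export
child_seed <- function(master_seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  state <- as.double(master_seed) %% m
  for (key in list(...)) {
    comps <- if (is.character(key)) as.double(utf8ToInt(key)) else as.double(key)
    for (k in comps) {
      # double arithmetic is exact here: state * 48271 < 2^31 * 48271 < 2^48
      state <- (state * 48271 + k) %% m
    }
  }
  as.integer(state %% (m - 2L) + 1L)
}

#' Run an expression under a local RNG seed
#'
#' Evaluates `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so library code never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
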