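#' @keywords internal
"_PACKAGE"

## All randomness in the package flows from one integer seed. Sub-generators
## (counts, placement, DAPI noise, ...) derive their own seeds through a
## counter-based split so they stay independently reproducible even when the
## amount of randomness one of them consumes changes.

#' Derive an independent child seed from a parent seed
#'
#' Deterministic splitting of a single run seed into per-component seeds.
#' Uses a multiplicative hash of the parent seed and a component counter,
#' reduced modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed parent seed (non-negative integer).
#' @param counter component index (non-negative integer), or a character
#'   label hashed to an index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  if (is.character(counter)) {
    counter <- sum(utf8ToInt(counter) * seq_along(utf8ToInt(counter)))
  }
  m <- 2147483647  # 2^31 - 1, prime
  ## two rounds of a Lehmer-style mix; all arithmetic kept in double range
  x <- (seed %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + counter %% m) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library code never perturbs user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

## internal: stop() with a condition class so callers can distinguish
## structured failures from generic errors
stop_with_class <- function(msg, class) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
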