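# Internal helpers shared across modules.

expit <- function(x) 1 / (1 + exp(-x))

#' Derive reproducible sub-seeds from a master seed
#'
#' Splits one master seed into `n` independent integer seeds so that each
#' pipeline stage (simulation, bootstrap, resampling) can be re-run in
#' isolation with its own seed.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(2147483645L, n)
}

# Stop with a classed condition so callers/tests can catch specific errors.
stop_mpe <- function(msg, class) {
  stop(structure(
    class = c(class, "mpescreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
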