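# Internal validation and RNG helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' Derive a stream-specific seed from a top-level seed
#'
#' All stochastic functions in the package draw their randomness from a
#' single user seed. Independent random streams (e.g. one per simulated
#' neuron) use sub-seeds produced by this mixing function, so that the
#' whole pipeline is reproducible from one integer.
#'
#' @param seed Integer top-level seed.
#' @param stream Integer stream index (>= 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  assert_number(seed, "seed")
  assert_number(stream, "stream", nonneg = TRUE)
  m <- 2147483629 # largest prime < 2^31
  s <- (as.double(seed) %% m)
  ((s * 69621 + as.double(stream) * 823543 + 1) %% m)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(derive_seed(seed)))
  }
  force(expr)
}
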