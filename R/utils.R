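# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that consume
#' randomness never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' Counter-based split: every stochastic sub-operation draws its own seed
#' from the master seed and a small integer counter, so stages are
#' independently reproducible. The result stays inside the positive
#' 32-bit integer range.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master),
            is.numeric(counter), length(counter) == 1, counter >= 0)
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- (abs(as.numeric(master)) %% m)
  # minimal-standard LCG step per counter increment keeps streams decorrelated
  s <- (s * 48271 + 1 + as.numeric(counter) * 7919) %% m
  as.integer(s %% (m - 2) + 1)
}

# canonical channel order used everywhere
bsfc_channels <- function() c("S405", "S488", "S633", "FP1", "FP2")
scatter_channels <- function() c("S405", "S488", "S633")

stop_bsfc <- function(...) stop(sprintf(...), call. = FALSE)
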