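# Internal helpers: structured conditions, seeded evaluation, count allocation.

cleavent_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cleavent_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Largest-remainder integer allocation
#'
#' Splits `n` units over categories proportionally to `probs` with total
#' exactly `n` and per-category error strictly below 1: each category gets
#' `floor(n * p)` and the remaining units go to the largest fractional
#' parts, ties broken by category order (alphabet order when `probs` is an
#' abundance table). This is what makes "expected counts" generator mode
#' deterministic and its entropy endpoints exact.
#'
#' @param n total count to allocate, non-negative integer.
#' @param probs non-negative weights, at least one positive; renormalized
#'   internally.
#' @return integer vector of the same length (and names) as `probs`,
#'   summing to `n`.
#' @export
#' @examples
#' allocate_counts(10, c(a = 1, b = 1, c = 1))
allocate_counts <- function(n, probs) {
  stopifnot(length(n) == 1L, n >= 0, all(probs >= 0), any(probs > 0))
  x <- n * probs / sum(probs)
  f <- floor(x)
  r <- round(n - sum(f))
  if (r > 0) {
    idx <- order(x - f, decreasing = TRUE)  # stable: ties fall to lower index
    f[idx[seq_len(r)]] <- f[idx[seq_len(r)]] + 1
  }
  stats::setNames(as.integer(f), names(probs))
}
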