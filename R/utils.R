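#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their (config, seed) arguments and never disturb the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.125 -> 0.13 at 2 decimals), the
#' convention used for the printed probability tables; base `round()` uses
#' round-half-even instead.
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Largest-remainder apportionment of n among proportions
#'
#' Rounds `n * p` to integers that sum exactly to `n`: take the floors, then
#' distribute the remaining units to the cells with the largest fractional
#' remainders (ties broken by cell order).
#' @keywords internal
largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
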