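# Internal helpers shared across modules.

# Signal a classed error so callers can distinguish censoring/degeneracy from
# programming mistakes (tryCatch on the subclass).
cvf_stop <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "cvf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so `round_half_away(0.5) == 1`), the convention used when formatting
#' printed percentages. Base `round()` rounds half to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run an expression with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
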