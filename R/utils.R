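# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (unlike [round()], which rounds half to even). A small relative
#' tolerance absorbs binary floating-point representation error so that
#' values sitting exactly on a .5 boundary in decimal arithmetic round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  scaled <- x * scale
  # nudge by a relative epsilon so exact decimal halves survive fp error
  eps <- 1e-8 * pmax(1, abs(scaled))
  sign(x) * floor(abs(scaled) + 0.5 + eps) / scale
}

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# global RNG state untouched; otherwise use the ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
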