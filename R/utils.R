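#' Wrap an angle difference into (-pi, pi]
#'
#' @param a angle in radians.
#' @return the equivalent angle in `(-pi, pi]`.
#' @keywords internal
wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi)
  out[out <= 0] <- out[out <= 0] + 2 * pi
  out - pi
}

# run code with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a named substream seed from a root seed (kept below 2^31)
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587)
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  stop_if(!all(is.finite(x)), sprintf("non-finite values in %s", what))
}
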