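#' Wrap angles into (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  # map -180 exactly to +180 so the interval is (-180, 180]
  y[y <= -180 + 1e-12 & y > -180 - 1e-12] <- 180
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Mid-range normalization to the unit interval
#'
#' Affine rescaling `v <- (v - min(v)) / (max(v) - min(v))` mapping a vector
#' (or a response pattern, see [interpolate_pattern()]) onto \[0, 1\]. This is
#' the single definition of "normalized firing rate" used throughout the
#' package (response patterns, model patterns, amplitude-response curves).
#'
#' @param x numeric vector/matrix, or a `response_pattern`.
#' @return object of the same shape. If `max(x) == min(x)` the result is all
#'   zeros and carries the attribute `degenerate = TRUE` (a `response_pattern`
#'   sets its `degenerate` field instead). Idempotent on non-degenerate input.
#' @examples
#' midrange_normalize(c(2, 4, 6)) # 0 0.5 1
#' @export
midrange_normalize <- function(x) {
  UseMethod("midrange_normalize")
}

#' @export
midrange_normalize.default <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite values in midrange_normalize()")
  if (rng[2] - rng[1] <= 0) {
    out <- x * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @export
midrange_normalize.response_pattern <- function(x) {
  v <- midrange_normalize(as.vector(x$values))
  x$degenerate <- isTRUE(attr(v, "degenerate"))
  x$values <- matrix(as.vector(v), nrow = nrow(x$values))
  x$normalized <- TRUE
  x
}

# Deterministic child-seed derivation so that per-stage / per-neuron /
# per-repeat RNG streams are stable when the population grows. Always < 2^31.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 69069 + 1234567 * (as.double(i) + 1)) %% 2147483647
  }
  as.integer(s)
}

# evaluate expr with a local RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation that tolerates zero-variance input (returns NA quietly)
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# constant up to rounding noise (barycentric weight sums are 1 +/- eps, so
# interpolating a constant leaves ~1e-16 relative ripples)
near_constant <- function(v) {
  diff(range(v)) <= 1e-9 * max(abs(v), 1e-300)
}
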