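# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; the declumping rule and the
#' noise-free count generator need the conventional "half up" rounding.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Trapezoidal quadrature
#' @param x abscissae (increasing).
#' @param y ordinates.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' library functions with internal randomness do not perturb user code.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stream of child seeds from a master seed
#'
#' Deterministic, collision-resistant enough for study-sized designs, and
#' kept below 2^31 so the values remain valid R integers.
#'
#' @keywords internal
derive_seeds <- function(seed, n) {
  as.integer((as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
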