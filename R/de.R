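#' Differential evolution on a box
#'
#' Classic rand/1/bin differential evolution, used as the inner global
#' optimiser that maximises acquisition functions on the (cheap) Kriging
#' surrogate. The objective must be vectorised over the rows of a matrix;
#' randomness is drawn from the caller's RNG stream so runs are
#' reproducible under a fixed seed.
#'
#' @param fn vectorised objective: takes an (m x d) matrix, returns m
#'   values. Minimised by default.
#' @param lower,upper bound vectors of length d.
#' @param pop_mult population size per dimension (population = `pop_mult
#'   * d`, at least 8).
#' @param generations number of generations.
#' @param F_weight differential weight.
#' @param CR crossover probability.
#' @param maximize set `TRUE` to maximise `fn`.
#' @param init optional matrix of points injected into the initial
#'   population (e.g. the current incumbent).
#' @return List with `par` (best point) and `value` (best objective on
#'   the minimisation scale used internally, negated back if maximising).
#' @export
de_optimize <- function(fn, lower, upper, pop_mult = 15, generations = 100,
                        F_weight = 0.8, CR = 0.9, maximize = FALSE,
                        init = NULL) {
  d <- length(lower)
  np <- max(8L, as.integer(pop_mult * d))
  span <- upper - lower
  pop <- matrix(stats::runif(np * d), np, d) *
    rep(span, each = np) + rep(lower, each = np)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    nkeep <- min(nrow(init), np)
    pop[seq_len(nkeep), ] <- init[seq_len(nkeep), , drop = FALSE]
  }
  sgn <- if (maximize) -1 else 1
  fit <- sgn * fn(pop)
  fit[!is.finite(fit)] <- Inf
  for (g in seq_len(generations)) {
    r1 <- sample.int(np); r2 <- sample.int(np); r3 <- sample.int(np)
    mutant <- pop[r1, , drop = FALSE] +
      F_weight * (pop[r2, , drop = FALSE] - pop[r3, , drop = FALSE])
    cross <- matrix(stats::runif(np * d) < CR, np, d)
    cross[cbind(seq_len(np), sample.int(d, np, replace = TRUE))] <- TRUE
    trial <- ifelse(cross, mutant, pop)
    # clip to the box
    trial <- pmin(pmax(trial, rep(lower, each = np)), rep(upper, each = np))
    tfit <- sgn * fn(trial)
    tfit[!is.finite(tfit)] <- Inf
    better <- tfit < fit
    pop[better, ] <- trial[better, , drop = FALSE]
    fit[better] <- tfit[better]
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = sgn * fit[best])
}
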