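#' Latin hypercube sample
#'
#' Space-filling design on the unit box: in every dimension exactly one
#' point falls in each of the `n` equal strata.
#'
#' @param n number of points (>= 1).
#' @param d number of dimensions (>= 1).
#' @param seed integer seed; the same seed reproduces the same design
#'   without disturbing the caller's RNG stream.
#' @return An (n x d) matrix in (0, 1)^d.
#' @export
latin_hypercube <- function(n, d, seed) {
  if (n < 1L || d < 1L) stop_domain("n and d must be >= 1")
  with_seed(seed, lhs::randomLHS(n, d))
}

#' Shrink a search box around an incumbent
#'
#' Domain-size reduction step of the surrogate optimiser: the box is
#' recentred on the incumbent with each width multiplied by
#' `shrink_factor`, then clipped back into the original box.
#'
#' @param bounds 2 x d matrix with rows `lower`, `upper`.
#' @param incumbent point inside `bounds`.
#' @param shrink_factor width multiplier in (0, 1).
#' @return New bounds matrix (subset of `bounds`).
#' @export
reduce_domain <- function(bounds, incumbent, shrink_factor) {
  if (shrink_factor <= 0 || shrink_factor >= 1)
    stop_domain("shrink_factor must lie in (0, 1)")
  lo <- bounds[1L, ]; hi <- bounds[2L, ]
  if (any(incumbent < lo - 1e-12) || any(incumbent > hi + 1e-12))
    stop_domain("incumbent outside bounds")
  w <- (hi - lo) * shrink_factor / 2
  new_lo <- pmax(incumbent - w, lo)
  new_hi <- pmin(incumbent + w, hi)
  rbind(lower = new_lo, upper = new_hi)
}

#' Propose a batch of candidate points from a Kriging surrogate
#'
#' Parallel-evaluation batch built from distinct sampling criteria: the
#' expected-improvement maximiser (found by differential evolution), the
#' predictive-mean minimiser (exploitation), the predictive-sd maximiser
#' (exploration), and further EI maximisers under the constant-liar
#' heuristic (each previous candidate is temporarily entered into the
#' surrogate at the incumbent value so that the next EI peak moves
#' elsewhere). Candidates closer than `dedupe_radius` to each other or to
#' a training point are replaced by uniform draws inside the bounds.
#'
#' @param model a [gp_fit()] surrogate (inputs in the unit box).
#' @param bounds 2 x d matrix of current search bounds.
#' @param q batch size (>= 1).
#' @param f_min current best observed objective (surrogate scale);
#'   defaults to the minimum of the training responses.
#' @param dedupe_radius minimum pairwise distance between proposals.
#' @param de_generations generations for the inner DE runs.
#' @return An (q x d) matrix with a `criterion` attribute (character
#'   vector naming the criterion that produced each row).
#' @export
propose_batch <- function(model, bounds, q, f_min = min(model$y),
                          dedupe_radius = 1e-3, de_generations = 100) {
  if (q < 1L) stop_domain("q must be >= 1")
  d <- ncol(model$X)
  lo <- bounds[1L, ]; hi <- bounds[2L, ]
  cand <- matrix(NA_real_, 0L, d)
  crit <- character(0)
  add <- function(x, label) {
    cand <<- rbind(cand, matrix(x, nrow = 1L))
    crit <<- c(crit, label)
  }
  add(de_optimize(function(M) gp_expected_improvement(model, M, f_min),
                  lo, hi, generations = de_generations,
                  maximize = TRUE)$par, "max_ei")
  if (q >= 2L)
    add(de_optimize(function(M) gp_predict(model, M)$mean, lo, hi,
                    generations = ceiling(de_generations * 0.6))$par,
        "min_mean")
  if (q >= 3L)
    add(de_optimize(function(M) gp_predict(model, M)$sd, lo, hi,
                    generations = ceiling(de_generations * 0.6),
                    maximize = TRUE)$par, "max_sd")
  if (q >= 4L) {
    liar <- model
    for (j in seq_len(q - 3L)) {
      liar <- gp_augment(liar, cand[1L, ], f_min)
      if (j > 1L) liar <- gp_augment(liar, cand[nrow(cand), ], f_min)
      add(de_optimize(function(M) gp_expected_improvement(liar, M, f_min),
                      lo, hi, generations = de_generations,
                      maximize = TRUE)$par, "liar_ei")
    }
  }
  # dedupe against training points and earlier candidates
  for (i in seq_len(nrow(cand))) {
    ref <- rbind(model$X, cand[seq_len(i - 1L), , drop = FALSE])
    tries <- 0L
    while (nrow(ref) &&
           min(sqrt(rowSums((ref - rep(cand[i, ], each = nrow(ref)))^2))) <
             dedupe_radius && tries < 50L) {
      cand[i, ] <- lo + stats::runif(d) * (hi - lo)
      crit[i] <- "random"
      tries <- tries + 1L
    }
  }
  structure(cand[seq_len(q), , drop = FALSE], criterion = crit[seq_len(q)])
}

#' Kriging-based global optimisation
#'
#' Surrogate-assisted minimisation of an expensive objective: an initial
#' Latin-hypercube design, then repeated cycles of (i) fitting an
#' ordinary-Kriging surrogate to a log10 transform of the observed
#' objective, (ii) proposing a batch of candidates by expected
#' improvement (maximised with differential evolution), predictive-mean
#' minimisation, predictive-sd maximisation and constant-liar EI, and
#' (iii) evaluating the true objective at the batch. After several
#' stagnant batches the search box is shrunk around the incumbent; the
#' run stops when the evaluation budget is exhausted or the maximal EI
#' falls below a relative tolerance.
#'
#' @param f objective function of a parameter vector, returning a finite
#'   scalar (large penalty values for failed evaluations are fine and are
#'   kept in the training set).
#' @param bounds 2 x d matrix with rows `lower`, `upper` (original
#'   parameter scale).
#' @param budget maximum number of true-objective evaluations (>= the
#'   initial design size).
#' @param q batch size per iteration.
#' @param seed integer seed controlling every random draw of the run.
#' @param n_init initial design size (default `10 * d`).
#' @param shrink_factor,stagnation,max_reductions domain-reduction rule:
#'   shrink by `shrink_factor` after `stagnation` consecutive batches
#'   whose relative improvement is below `1e-3`, at most
#'   `max_reductions` times.
#' @param ei_tol_rel stop when max EI < `ei_tol_rel * |incumbent|` (on
#'   the surrogate's transformed scale).
#' @param log10_transform fit the surrogate to `log10(f + eps)` (the
#'   objective must then be nonnegative); recommended for sum-of-squares
#'   objectives whose scale spans decades.
#' @param de_generations generations of the inner DE acquisition search.
#' @return An object of class `krig_result`: list with `par` and `value`
#'   (incumbent on the original scale), `history` (one row per
#'   evaluation: iteration, criterion, parameters, objective),
#'   `bounds_final`, `termination`, `n_eval`, `seed`.
#' @export
#' @examples
#' f <- function(x) sum((x - 0.3)^2)
#' res <- krig_optimize(f, rbind(0, 1) %x% t(rep(1, 2)), budget = 40,
#'                      seed = 1, n_init = 12)
#' res$value
krig_optimize <- function(f, bounds, budget = 500, q = 4, seed = 1,
                          n_init = NULL, shrink_factor = 0.5,
                          stagnation = 5, max_reductions = 4,
                          ei_tol_rel = 1e-6, log10_transform = TRUE,
                          de_generations = 100) {
  d <- ncol(bounds)
  lo0 <- bounds[1L, ]; hi0 <- bounds[2L, ]
  if (any(!is.finite(lo0)) || any(!is.finite(hi0)) || any(lo0 >= hi0))
    stop_domain("bounds must be finite with lower < upper")
  if (is.null(n_init)) n_init <- 10L * d
  if (budget < n_init)
    stop_domain("budget (", budget, ") smaller than the initial design (",
                n_init, ")")
  to_x <- function(U) {
    U <- matrix(U, ncol = d)
    U * rep(hi0 - lo0, each = nrow(U)) + rep(lo0, each = nrow(U))
  }
  eval_f <- function(U, iter, criterion) {
    X <- to_x(U)
    vals <- vapply(seq_len(nrow(X)), function(i) {
      v <- f(X[i, ])
      if (!is.finite(v)) stop("objective returned a non-finite value at (",
                              paste(signif(X[i, ], 4), collapse = ", "), ")",
                              call. = FALSE)
      as.numeric(v)
    }, 0)
    hist_new <- data.frame(iteration = iter, criterion = criterion,
                           objective = vals)
    hist_new <- cbind(hist_new, as.data.frame(X))
    list(vals = vals, hist = hist_new)
  }
  with_seed(seed, {
    U <- lhs::randomLHS(n_init, d)
    ev <- eval_f(U, 0L, "lhs_init")
    y <- ev$vals
    history <- ev$hist
    termination <- "budget"
    cur <- rbind(lower = rep(0, d), upper = rep(1, d))
    reductions <- 0L
    stagnant <- 0L
    iter <- 0L
    while (length(y) < budget) {
      iter <- iter + 1L
      if (log10_transform) {
        if (any(y < 0))
          stop_domain("log10 transform requires a nonnegative objective")
        eps <- 1e-12 + 1e-10 * stats::median(abs(y))
        yt <- log10(y + eps)
      } else yt <- y
      model <- suppressWarnings(gp_fit(U, yt))
      f_min_t <- min(yt)
      qq <- min(q, budget - length(y))
      cand <- propose_batch(model, cur, qq,
                            de_generations = de_generations)
      max_ei <- max(gp_expected_improvement(model, cand, f_min_t))
      if (max_ei < ei_tol_rel * abs(f_min_t)) {
        termination <- "ei_tolerance"
        break
      }
      before <- min(y)
      ev <- eval_f(cand, iter, attr(cand, "criterion"))
      U <- rbind(U, cand)
      y <- c(y, ev$vals)
      history <- rbind(history, ev$hist)
      rel_impr <- (before - min(y)) / max(abs(before), 1e-12)
      if (rel_impr < 1e-3) stagnant <- stagnant + 1L else stagnant <- 0L
      if (stagnant >= stagnation && reductions < max_reductions) {
        cur <- reduce_domain(cur, U[which.min(y), ], shrink_factor)
        reductions <- reductions + 1L
        stagnant <- 0L
      }
    }
    best <- which.min(y)
    X_all <- to_x(U)
    colnames(history)[-(1:3)] <- colnames(bounds) %||%
      paste0("par", seq_len(d))
    history[, -(1:3)] <- X_all
    structure(list(
      par = X_all[best, ], value = y[best],
      history = history,
      bounds_final = rbind(lower = to_x(cur[1L, ])[1L, ],
                           upper = to_x(cur[2L, ])[1L, ]),
      termination = termination, n_eval = length(y),
      n_reductions = reductions, seed = seed
    ), class = "krig_result")
  })
}

#' @export
print.krig_result <- function(x, ...) {
  cat(sprintf(
    "<krig_result> incumbent %.6g after %d evaluations (%s); par = (%s)\n",
    x$value, x$n_eval, x$termination,
    paste(signif(x$par, 5), collapse = ", ")))
  invisible(x)
}

#' Fit the infiltration model to binned count data
#'
#' Convenience wrapper tying [infil_objective()] to [krig_optimize()]:
#' each well is fitted separately by minimising the sum-of-squares
#' distance between observed and predicted bin counts over the free
#' parameters declared in the fit specification.
#'
#' @param data a `binned_counts` object.
#' @param spec a [fit_spec()].
#' @param budget,q,seed,... passed to [krig_optimize()].
#' @return A `krig_result`; `par` is reported on the natural parameter
#'   scale (log10 entries back-transformed) in `par_natural`.
#' @export
fit_infiltration <- function(data, spec, budget = 200, q = 4, seed = 1, ...) {
  b <- fit_bounds(spec)
  colnames(b) <- names(spec$free)
  res <- krig_optimize(function(theta) infil_objective(data, spec, theta),
                       b, budget = budget, q = q, seed = seed, ...)
  nat <- res$par
  islog <- vapply(spec$free, function(f) f$log10, TRUE)
  nat[islog] <- 10^nat[islog]
  names(nat) <- names(spec$free)
  res$par_natural <- nat
  res
}
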