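# Ordinary Kriging with an anisotropic Matern-5/2 kernel.
#
# Written for the surrogate optimiser: inputs live in the unit box, the
# trend is an unknown constant, hyperparameters are estimated by profile
# maximum likelihood over per-dimension length scales, and predictions
# return both mean and standard deviation.

matern52_cor <- function(X1, X2, ls) {
  d <- ncol(X1)
  r2 <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(d)) {
    dj <- outer(X1[, j], X2[, j], "-") / ls[j]
    r2 <- r2 + dj * dj
  }
  r <- sqrt(r2) * sqrt(5)
  (1 + r + r * r / 3) * exp(-r)
}

# Cholesky with automatic nugget escalation for near-singular matrices.
chol_with_nugget <- function(R, nugget) {
  for (trial in 0:6) {
    L <- tryCatch(chol(R + diag(nugget, nrow(R))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, nugget = nugget, escalated = trial > 0))
    nugget <- max(nugget, 1e-12) * 100
  }
  stop("covariance matrix not positive definite even after nugget escalation",
       call. = FALSE)
}

# Profile negative log likelihood over length scales (y standardised).
gp_nll <- function(log_ls, X, y, nugget) {
  R <- matern52_cor(X, X, exp(log_ls))
  ch <- tryCatch(chol_with_nugget(R, nugget), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  L <- ch$L
  n <- length(y)
  one <- rep(1, n)
  Li_y <- backsolve(L, y, transpose = TRUE)
  Li_1 <- backsolve(L, one, transpose = TRUE)
  beta <- sum(Li_1 * Li_y) / sum(Li_1 * Li_1)
  resid <- Li_y - beta * Li_1
  sigma2 <- max(sum(resid^2) / n, 1e-300)
  n / 2 * log(sigma2) + sum(log(diag(L)))
}

#' Fit an ordinary-Kriging surrogate
#'
#' Gaussian-process interpolator with constant trend and anisotropic
#' Matern-5/2 correlation. Per-dimension length scales are estimated by
#' maximising the profile marginal likelihood from several restarts; the
#' constant trend and process variance have closed-form profile
#' estimates. A small nugget regularises the correlation matrix and is
#' escalated automatically (with a warning) when it is numerically
#' singular, e.g. for near-duplicate design points.
#'
#' @param X numeric matrix of training inputs (rows = points), ideally
#'   scaled to the unit box.
#' @param y numeric vector of training responses.
#' @param nugget diagonal regularisation (default `1e-10`; with this value
#'   the predictive mean interpolates the data).
#' @param restarts number of likelihood-maximisation restarts.
#' @param ls_bounds allowed length-scale range.
#' @return An object of class `krig_model`.
#' @export
#' @examples
#' X <- matrix(runif(30), ncol = 2)
#' m <- gp_fit(X, rowSums(X^2))
#' gp_predict(m, X)$mean - rowSums(X^2)  # ~0: interpolation
gp_fit <- function(X, y, nugget = 1e-10, restarts = 5,
                   ls_bounds = c(0.05, 2)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  if (n < d + 2L) stop_domain("need at least d + 2 training points")
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop_domain("training data must be finite")
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  constant <- !is.finite(sd_y) || sd_y < 1e-12 * (abs(mu_y) + 1)
  if (constant) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  lb <- log(ls_bounds[1L]); ub <- log(ls_bounds[2L])
  starts <- matrix(stats::runif(restarts * d, lb + 0.15 * (ub - lb),
                                lb + 0.7 * (ub - lb)), ncol = d)
  starts[1L, ] <- rep(log(0.5), d)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- try(stats::optim(starts[i, ], gp_nll, X = X, y = ys,
                           nugget = nugget, method = "L-BFGS-B",
                           lower = lb, upper = ub,
                           control = list(maxit = 60)), silent = TRUE)
    if (!inherits(op, "try-error") &&
        (is.null(best) || op$value < best$value)) best <- op
  }
  ls <- if (is.null(best)) rep(0.5, d) else exp(best$par)
  R <- matern52_cor(X, X, ls)
  ch <- chol_with_nugget(R, nugget)
  if (ch$escalated)
    warning("ill-conditioned Kriging covariance: nugget escalated to ",
            format(ch$nugget), call. = FALSE)
  L <- ch$L
  one <- rep(1, n)
  Li_y <- backsolve(L, ys, transpose = TRUE)
  Li_1 <- backsolve(L, one, transpose = TRUE)
  s11 <- sum(Li_1 * Li_1)
  beta <- sum(Li_1 * Li_y) / s11
  resid_w <- Li_y - beta * Li_1
  sigma2 <- if (constant) 0 else sum(resid_w^2) / n
  structure(list(
    X = X, y = y, mu_y = mu_y, sd_y = sd_y, beta = beta, sigma2 = sigma2,
    lengthscales = ls, nugget = ch$nugget, L = L,
    alpha = backsolve(L, resid_w), Li_1 = Li_1, s11 = s11,
    constant = constant
  ), class = "krig_model")
}

#' @export
print.krig_model <- function(x, ...) {
  cat(sprintf("<krig_model> n = %d, d = %d; lengthscales = %s; nugget = %g\n",
              nrow(x$X), ncol(x$X),
              paste(signif(x$lengthscales, 3), collapse = ", "), x$nugget))
  invisible(x)
}

#' Kriging prediction
#'
#' Predictive mean and standard deviation at new points, including the
#' ordinary-Kriging correction for the estimated constant trend.
#'
#' @param model a [gp_fit()] object.
#' @param Xnew matrix of query points (rows), or a single point vector.
#' @return List with numeric vectors `mean` and `sd`.
#' @export
gp_predict <- function(model, Xnew) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1L)
  Xnew <- as.matrix(Xnew)
  r <- matern52_cor(model$X, Xnew, model$lengthscales)   # n x m
  mean <- model$mu_y + model$sd_y *
    (model$beta + drop(crossprod(r, model$alpha)))
  if (model$sigma2 <= 0) return(list(mean = mean, sd = rep(0, nrow(Xnew))))
  Li_r <- backsolve(model$L, r, transpose = TRUE)
  quad <- colSums(Li_r^2)
  trend <- (1 - drop(crossprod(Li_r, model$Li_1)))^2 / model$s11
  var_s <- model$sigma2 * pmax(1 - quad + trend, 0)
  list(mean = mean, sd = model$sd_y * sqrt(var_s))
}

# Rebuild the factorisation with an extra (x, y) pair, keeping the fitted
# hyperparameters: used for constant-liar batch proposals.
gp_augment <- function(model, xnew, ynew) {
  X <- rbind(model$X, matrix(xnew, nrow = 1L))
  y <- c(model$y, ynew)
  n <- nrow(X)
  ys <- (y - model$mu_y) / model$sd_y
  R <- matern52_cor(X, X, model$lengthscales)
  ch <- chol_with_nugget(R, model$nugget)
  L <- ch$L
  one <- rep(1, n)
  Li_y <- backsolve(L, ys, transpose = TRUE)
  Li_1 <- backsolve(L, one, transpose = TRUE)
  s11 <- sum(Li_1 * Li_1)
  beta <- sum(Li_1 * Li_y) / s11
  resid_w <- Li_y - beta * Li_1
  m <- model
  m$X <- X; m$y <- y; m$beta <- beta; m$L <- L
  m$sigma2 <- if (model$constant) 0 else sum(resid_w^2) / n
  m$alpha <- backsolve(L, resid_w); m$Li_1 <- Li_1; m$s11 <- s11
  m$nugget <- ch$nugget
  m
}

#' Expected improvement
#'
#' Closed-form expected improvement of a Gaussian predictive distribution
#' over the current best value `f_min` (for minimisation):
#' \eqn{EI = (f_{min}-\mu)\Phi(z) + \sigma\phi(z)} with
#' \eqn{z = (f_{min}-\mu)/\sigma}; for \eqn{\sigma = 0} it degenerates to
#' \eqn{\max(0, f_{min}-\mu)}.
#'
#' @param mu predictive mean(s).
#' @param sd predictive standard deviation(s), >= 0.
#' @param f_min current best observed value.
#' @return Nonnegative EI value(s).
#' @export
#' @examples
#' expected_improvement(0, 1, 0)  # = dnorm(0) ~ 0.3989
expected_improvement <- function(mu, sd, f_min) {
  if (any(sd < 0)) stop_domain("sd must be >= 0")
  imp <- f_min - mu
  ei <- pmax(imp, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- imp[pos] / sd[pos]
    ei[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(ei, 0)
}

#' @rdname expected_improvement
#' @param model a [gp_fit()] object.
#' @param Xnew query point(s).
#' @export
gp_expected_improvement <- function(model, Xnew, f_min) {
  pr <- gp_predict(model, Xnew)
  expected_improvement(pr$mean, pr$sd, f_min)
}
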