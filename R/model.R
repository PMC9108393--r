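#' Receptor-law chemotactic sensitivity
#'
#' Evaluates \eqn{\chi(x, \alpha) = \tilde\chi(x)\,k/(k+\alpha)^2}, where
#' the chemotactic scale \eqn{\tilde\chi} equals `chi_bar` in the middle
#' (matrix) channel and `chi_bar / mu_rho` in the top (epithelial) channel.
#' The receptor law captures the saturation of gradient sensing: at high
#' attractant concentration cells can no longer resolve the gradient and
#' the sensitivity decays like \eqn{1/\alpha^2}.
#'
#' @param x position(s) in \[0, 1\]; values at exactly `x_t` take the
#'   middle-channel scale.
#' @param alpha chemoattractant concentration(s), >= 0.
#' @param params an [model_params()] object.
#' @return Sensitivity values, recycled to the common length of `x` and
#'   `alpha`.
#' @export
#' @examples
#' p <- default_params()
#' chemotactic_sensitivity(0.1, 0, p)  # = chi_bar / k
chemotactic_sensitivity <- function(x, alpha, params) {
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop_domain("alpha must be finite and >= 0")
  if (any(x < 0 | x > 1)) stop_domain("x must lie in [0, 1]")
  if (params$k <= 0) stop_domain("receptor saturation constant k must be > 0")
  chit <- ifelse(x > params$x_t, params$chi_bar / params$mu_rho,
                 params$chi_bar)
  chit * params$k / (params$k + alpha)^2
}

#' Steady-state chemoattractant profile (finite-volume solve)
#'
#' Computes the initial condition for the chemoattractant: the steady
#' state of its linear reaction-diffusion balance in the absence of cells,
#' \deqn{0 = \partial_x(D_\alpha(x)\partial_x\bar\alpha)
#'       + \eta_1 1_{x<x_t} - \nu\bar\alpha,}
#' with the Robin leak \eqn{\partial_x\alpha = \zeta\alpha} at `x = 0` and
#' zero flux at `x = 1`. The profile is obtained by solving the linear
#' system on the same finite-volume stencil as the time-dependent solver,
#' so the discrete time derivative of alpha vanishes identically at `t = 0`.
#'
#' @param params an [model_params()] object.
#' @param grid an [spatial_grid()] object.
#' @return Numeric vector of cell-averaged steady concentrations.
#' @seealso [alpha_steady_closed_form()] for the analytic two-region
#'   solution used as an independent cross-check.
#' @export
steady_state_alpha <- function(params, grid) {
  n <- grid$n_cells; h <- grid$h
  co <- grid_coefficients(params, grid)
  b <- ifelse(co$mid, params$eta1, 0)
  if (params$nu == 0 && params$zeta == 0) {
    if (all(b == 0)) return(rep(0, n))
    stop_domain("no steady state exists: nu = zeta = 0 with eta1 > 0 ",
                "(production is never removed)")
  }
  Df <- co$Da_face / h^2                    # interior faces 1..n-1
  diag_v <- params$nu + c(Df, 0) + c(0, Df)
  # Robin leak at x = 0 via the one-sided face value alpha_face =
  # alpha_1 / (1 + zeta h / 2)
  diag_v[1L] <- diag_v[1L] +
    params$D_alpha_bar * params$zeta / ((1 + params$zeta * h / 2) * h)
  A <- diag(diag_v)
  A[cbind(1:(n - 1L), 2:n)] <- -Df
  A[cbind(2:n, 1:(n - 1L))] <- -Df
  ab <- solve(A, b)
  pmax(ab, 0)
}

#' Analytic steady-state chemoattractant profile
#'
#' Closed-form solution of the two-region steady problem solved by
#' [steady_state_alpha()], valid for `nu > 0`. In the producing matrix
#' channel the solution is \eqn{\eta_1/\nu + A\cosh(m_1 x) + B\sinh(m_1 x)}
#' with \eqn{m_1 = \sqrt{\nu/\bar D_\alpha}}; in the epithelial channel it
#' is \eqn{C\cosh(m_2(1-x))} with \eqn{m_2 = \sqrt{\nu\mu_\alpha/\bar
#' D_\alpha}}, which satisfies the zero-flux condition at `x = 1` by
#' construction. The three constants follow from the Robin condition at
#' `x = 0` and continuity of concentration and diffusive flux at `x_t`.
#' Assembled independently of the finite-volume stencil; used as the
#' convergence oracle for the discrete solver.
#'
#' @param params an [model_params()] object with `nu > 0`.
#' @param x positions at which to evaluate the profile.
#' @return Numeric vector of concentrations at `x`.
#' @export
alpha_steady_closed_form <- function(params, x) {
  if (params$nu <= 0)
    stop_domain("closed-form steady state requires nu > 0")
  D1 <- params$D_alpha_bar
  D2 <- params$D_alpha_bar / params$mu_alpha
  m1 <- sqrt(params$nu / D1)
  m2 <- sqrt(params$nu / D2)
  P <- params$eta1 / params$nu
  xt <- params$x_t; zeta <- params$zeta
  # Top-channel branch normalised by cosh(m2 (1 - xt)) so the system stays
  # well conditioned for steep epithelial decay (large m2); the ratio of
  # cosh terms is evaluated in log space to avoid overflow.
  logcosh <- function(z) abs(z) + log1p(exp(-2 * abs(z))) - log(2)
  # unknowns (A, B, C) with C = alpha(xt+) directly
  M <- rbind(
    c(-zeta, m1, 0),                                   # B m1 = zeta (P + A)
    c(cosh(m1 * xt), sinh(m1 * xt), -1),
    c(D1 * m1 * sinh(m1 * xt), D1 * m1 * cosh(m1 * xt),
      D2 * m2 * tanh(m2 * (1 - xt)))
  )
  rhs <- c(zeta * P, -P, 0)
  abc <- solve(M, rhs)
  ifelse(x < xt,
         P + abc[1L] * cosh(m1 * x) + abc[2L] * sinh(m1 * x),
         abc[3L] * exp(logcosh(m2 * (1 - x)) - logcosh(m2 * (1 - xt))))
}

# Core finite-volume right-hand side on (rho, alpha) vectors.
# Fluxes are outward-positive in +x; chemotactic transport is upwinded on
# rho for positivity; diffusive face coefficients use harmonic means.
fv_rhs <- function(rho, alpha, params, grid, co) {
  n <- grid$n_cells; h <- grid$h
  k <- params$k
  dadx <- (alpha[-1L] - alpha[-n]) / h            # interior faces
  aface <- 0.5 * (alpha[-1L] + alpha[-n])
  u <- co$chi_face * k / (k + aface)^2 * dadx     # chemotactic velocity
  rho_up <- ifelse(u > 0, rho[-n], rho[-1L])
  F_rho_int <- -co$Dr_face * (rho[-1L] - rho[-n]) / h + u * rho_up
  # x = 0: chemotactically driven influx from the bottom-channel pool
  af0 <- alpha[1L] / (1 + params$zeta * h / 2)
  chi0 <- params$chi_bar * k / (k + af0)^2
  J0 <- chi0 * params$zeta * af0 * params$rho_tilde
  F_rho <- c(J0, F_rho_int, 0)
  drho <- -(F_rho[-1L] - F_rho[-(n + 1L)]) / h - params$xi * rho
  F_alpha_int <- -co$Da_face * (alpha[-1L] - alpha[-n]) / h
  F_alpha <- c(-params$D_alpha_bar * params$zeta * af0, F_alpha_int, 0)
  dalpha <- -(F_alpha[-1L] - F_alpha[-(n + 1L)]) / h +
    ifelse(co$mid, params$eta1, params$eta2 * rho) -
    params$kappa * rho * alpha - params$nu * alpha
  list(drho = drho, dalpha = dalpha, influx = J0,
       alpha_outflux = params$D_alpha_bar * params$zeta * af0)
}

#' Finite-volume right-hand side of the infiltration system
#'
#' Time derivatives of the cell density and chemoattractant fields for a
#' given state snapshot: the discrete divergence of diffusive plus
#' upwinded chemotactic fluxes, the reaction terms, and the boundary
#' fluxes (chemotactic PBMC influx and diffusive chemoattractant leak at
#' `x = 0`; zero total flux at `x = 1`).
#'
#' @param rho,alpha state vectors of length `grid$n_cells`.
#' @param params an [model_params()] object.
#' @param grid an [spatial_grid()] object.
#' @return List with `drho`, `dalpha`, and the instantaneous boundary
#'   fluxes `influx` (PBMC entry rate at `x = 0`) and `alpha_outflux`
#'   (outward-positive chemoattractant leak).
#' @export
infil_rhs <- function(rho, alpha, params, grid) {
  if (length(rho) != grid$n_cells || length(alpha) != grid$n_cells)
    stop_domain("state dimensions do not match the grid")
  if (any(!is.finite(rho)) || any(!is.finite(alpha)))
    stop_domain("non-finite state values")
  fv_rhs(rho, alpha, params, grid, grid_coefficients(params, grid))
}

#' Simulate the infiltration model
#'
#' Integrates the reaction-diffusion-chemotaxis system by the method of
#' lines from the empty-domain initial condition (`rho = 0`, alpha at its
#' macrophage-production steady state) using an adaptive stiff integrator
#' (lsoda with a banded Jacobian on interleaved state).
#'
#' @param params an [model_params()] object.
#' @param grid an [spatial_grid()] object, or an integer cell count (a
#'   grid is then built with the interface at `params$x_t`).
#' @param output_times increasing vector of output times in hours,
#'   starting at 0.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `infil_solution`: list with `times`, `x`
#'   (cell centers), matrices `rho` and `alpha` (times x cells),
#'   `influx_record` and `alpha_outflux_record` (boundary fluxes at the
#'   output times), `total_cells` (the spatial integral of rho per output
#'   time), plus the grid and parameters used.
#' @export
#' @examples
#' sol <- simulate_infiltration(default_params(), 50, seq(0, 8, by = 2))
#' sol$total_cells
simulate_infiltration <- function(params, grid, output_times,
                                  rtol = 1e-6, atol = 1e-9) {
  if (!inherits(grid, "infil_grid")) grid <- spatial_grid(grid, params$x_t)
  output_times <- as.numeric(output_times)
  if (length(output_times) < 1L || output_times[1L] != 0 ||
      is.unsorted(output_times, strictly = TRUE) || any(output_times < 0))
    stop_domain("output_times must be nonnegative, strictly increasing, and start at 0")
  n <- grid$n_cells
  co <- grid_coefficients(params, grid)
  alpha0 <- steady_state_alpha(params, grid)
  ir <- seq(1L, 2L * n, by = 2L)   # interleaved indices: rho
  ia <- ir + 1L                    # alpha
  y0 <- numeric(2L * n)
  y0[ia] <- alpha0
  deriv <- function(t, y, parms) {
    d <- fv_rhs(y[ir], y[ia], params, grid, co)
    dy <- numeric(2L * n)
    dy[ir] <- d$drho
    dy[ia] <- d$dalpha
    list(dy)
  }
  out <- deSolve::ode(y = y0, times = output_times, func = deriv,
                      parms = NULL, method = "lsoda",
                      jactype = "bandint", bandup = 3L, banddown = 2L,
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1L]
  if (nrow(out) < length(output_times) || (!is.null(istate) && istate < 0))
    stop("PDE integration failed (istate = ", istate, "); ",
         "last time reached: ", out[nrow(out), 1L], call. = FALSE)
  states <- out[, -1L, drop = FALSE]
  rho <- states[, ir, drop = FALSE]
  alpha <- states[, ia, drop = FALSE]
  dimnames(rho) <- dimnames(alpha) <- NULL
  # project integrator noise onto the invariant set: negatives within
  # 10x atol are solver chatter, not dynamics
  clamp <- function(m) { m[m < 0 & m > -10 * atol] <- 0; m }
  rho <- clamp(rho); alpha <- clamp(alpha)
  af0 <- alpha[, 1L] / (1 + params$zeta * grid$h / 2)
  chi0 <- params$chi_bar * params$k / (params$k + af0)^2
  structure(list(
    times = output_times, x = grid$centers, rho = rho, alpha = alpha,
    influx_record = chi0 * params$zeta * af0 * params$rho_tilde,
    alpha_outflux_record = params$D_alpha_bar * params$zeta * af0,
    total_cells = rowSums(rho) * grid$h,
    grid = grid, params = params
  ), class = "infil_solution")
}

#' @export
print.infil_solution <- function(x, ...) {
  cat(sprintf(
    "<infil_solution> %d times (0..%g h), %d cells; final total = %.2f cells\n",
    length(x$times), max(x$times), x$grid$n_cells,
    x$total_cells[length(x$total_cells)]))
  invisible(x)
}

#' Long-format view of a solution
#'
#' @param x an `infil_solution`.
#' @param ... unused.
#' @return Data frame with columns `time_h`, `x`, `rho`, `alpha`.
#' @export
as.data.frame.infil_solution <- function(x, ...) {
  data.frame(
    time_h = rep(x$times, each = length(x$x)),
    x = rep(x$x, times = length(x$times)),
    rho = as.vector(t(x$rho)),
    alpha = as.vector(t(x$alpha))
  )
}

#' Write a solution as CSV (long format)
#'
#' @param solution an `infil_solution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  utils::write.csv(as.data.frame(solution), path, row.names = FALSE)
  invisible(path)
}
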