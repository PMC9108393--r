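# Shared fixtures and independent oracles for the test suite.

# A smooth, well-resolved parameter set for discretisation-accuracy tests:
# moderate coefficient contrast and an interface position exactly
# representable on all tested grids (0.4 * N integer for N in 50..400).
smooth_params <- function() {
  model_params(
    D_rho_bar = 5e-3, D_alpha_bar = 0.2, chi_bar = 1,
    mu_rho = 4, mu_alpha = 5, xi = 0.05,
    eta1 = 1, eta2 = 0, kappa = 1e-3, nu = 1,
    k = 1, zeta = 0.5, rho_tilde = 50, x_t = 0.4
  )
}

# Independent steady-state oracle: solve the two-region boundary-value
# problem by brute-force collocation on a very fine uniform second-order
# finite-difference grid, assembled without any package FV machinery.
# Used to cross-check alpha_steady_closed_form itself.
steady_oracle_fd <- function(params, x_out, n_fd = 20000L) {
  h <- 1 / n_fd
  x <- seq(h / 2, 1 - h / 2, by = h)
  D <- ifelse(x < params$x_t, params$D_alpha_bar,
              params$D_alpha_bar / params$mu_alpha)
  Dface <- 2 * D[-1] * D[-n_fd] / (D[-1] + D[-n_fd])
  diag_v <- params$nu + (c(Dface, 0) + c(0, Dface)) / h^2
  diag_v[1] <- diag_v[1] +
    params$D_alpha_bar * params$zeta / ((1 + params$zeta * h / 2) * h)
  lowr <- -Dface / h^2
  uppr <- -Dface / h^2
  b <- ifelse(x < params$x_t, params$eta1, 0)
  # Thomas algorithm (the system is tridiagonal)
  cp <- numeric(n_fd); dp <- numeric(n_fd)
  cp[1] <- uppr[1] / diag_v[1]; dp[1] <- b[1] / diag_v[1]
  for (i in 2:n_fd) {
    m <- diag_v[i] - lowr[i - 1] * cp[i - 1]
    cp[i] <- if (i < n_fd) uppr[i] / m else 0
    dp[i] <- (b[i] - lowr[i - 1] * dp[i - 1]) / m
  }
  sol <- numeric(n_fd)
  sol[n_fd] <- dp[n_fd]
  for (i in (n_fd - 1):1) sol[i] <- dp[i] - cp[i] * sol[i + 1]
  stats::approx(x, sol, xout = x_out, rule = 2)$y
}

# Minimal hand-built solution object for expected_counts tests.
fake_solution <- function(rho_rows, times, n_cells, x_t = 0.5) {
  g <- spatial_grid(n_cells, x_t)
  structure(list(times = times, x = g$centers,
                 rho = rho_rows,
                 alpha = matrix(0, nrow(rho_rows), n_cells),
                 grid = g),
            class = "infil_solution")
}

# Small, fast study design for pipeline tests.
small_design <- function(...) {
  study_design(n_control = 2L, n_toxic = 2L, horizon_h = 24,
               n_cells = 100L, seed = 42L, ...)
}
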