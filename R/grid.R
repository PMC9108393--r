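#' Uniform finite-volume grid on the unit interval
#'
#' Builds the spatial discretisation used by the solver: `n_cells` volumes
#' of equal width on \[0, 1\]. The channel interface `x_t` is snapped onto
#' the nearest interior cell face so that the piecewise-constant motility
#' coefficients are discontinuous exactly at a face and every cell lies
#' unambiguously in one channel.
#'
#' @param n_cells number of finite volumes (>= 4).
#' @param x_t nominal interface position in (0, 1).
#' @return An object of class `infil_grid` with components `n_cells`, `h`
#'   (cell width), `centers`, `faces`, `iface` (index into `faces` of the
#'   interface face) and `x_t` (the snapped interface position).
#' @export
#' @examples
#' g <- spatial_grid(200, 0.35)
#' g$faces[g$iface]  # exactly 0.35
spatial_grid <- function(n_cells, x_t) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 4L)
    stop_domain("n_cells must be an integer >= 4")
  if (!is.finite(x_t) || x_t <= 0 || x_t >= 1)
    stop_domain("x_t must lie strictly inside (0, 1)")
  h <- 1 / n_cells
  faces <- seq(0, 1, length.out = n_cells + 1L)
  # nearest interior face (faces 2..n_cells in R indexing)
  iface <- round(x_t * n_cells) + 1L
  iface <- min(max(iface, 2L), n_cells)
  structure(list(
    n_cells = n_cells, h = h,
    centers = (seq_len(n_cells) - 0.5) * h,
    faces = faces, iface = iface, x_t = faces[iface]
  ), class = "infil_grid")
}

#' @export
print.infil_grid <- function(x, ...) {
  cat(sprintf("<infil_grid> %d cells, h = %g, interface at x = %g (face %d)\n",
              x$n_cells, x$h, x$x_t, x$iface))
  invisible(x)
}

# Piecewise-constant per-cell coefficients and harmonic-mean face values.
# The harmonic mean is exact for the flux across the coefficient jump at
# the interface face; elsewhere both neighbours are equal and it reduces
# to the common value.
grid_coefficients <- function(params, grid) {
  mid <- grid$centers < grid$x_t            # cells in the matrix channel
  Dr_c <- ifelse(mid, params$D_rho_bar, params$D_rho_bar / params$mu_rho)
  Da_c <- ifelse(mid, params$D_alpha_bar, params$D_alpha_bar / params$mu_alpha)
  ch_c <- ifelse(mid, params$chi_bar, params$chi_bar / params$mu_rho)
  hmean <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  n <- grid$n_cells
  list(
    mid = mid,
    Dr_face = hmean(Dr_c[-n], Dr_c[-1L]),   # interior faces 1..n-1
    Da_face = hmean(Da_c[-n], Da_c[-1L]),
    chi_face = hmean(ch_c[-n], ch_c[-1L])
  )
}
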