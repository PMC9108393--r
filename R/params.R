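#' Model parameters for the infiltration PDE system
#'
#' Bundles every parameter of the reaction-diffusion-chemotaxis model of
#' PBMC infiltration. Space is nondimensionalised to the unit interval
#' covering the matrix (middle) channel and the epithelial (top) channel,
#' with the channel interface at `x_t`; time is in hours.
#'
#' The PBMC density rho obeys
#' \deqn{\partial_t \rho = \partial_x(D_\rho(x)\partial_x\rho)
#'   - \partial_x(\chi(x,\alpha)\,\rho\,\partial_x\alpha) - \xi\rho,}
#' and the chemoattractant alpha
#' \deqn{\partial_t \alpha = \partial_x(D_\alpha(x)\partial_x\alpha)
#'   + \eta_1 1_{x<x_t} + \eta_2\rho 1_{x>x_t} - \kappa\rho\alpha - \nu\alpha.}
#' Motilities are piecewise constant: in the top channel \eqn{D_\rho} and the
#' chemotactic scale are divided by `mu_rho`, and \eqn{D_\alpha} by
#' `mu_alpha` (both > 1: the epithelium is less permissive than the matrix).
#' The chemotactic sensitivity follows the receptor law
#' \eqn{\chi(x,\alpha) = \tilde\chi(x)\, k/(k+\alpha)^2}.
#'
#' Boundary conditions: zero total flux for both species at `x = 1`; at
#' `x = 0` the PBMC influx is chemotactically driven,
#' \eqn{\chi(0,\alpha_0)\,\zeta\,\alpha_0\,\tilde\rho}, and the
#' chemoattractant leaks diffusively, \eqn{\partial_x\alpha = \zeta\alpha}.
#'
#' @param D_rho_bar middle-channel PBMC diffusivity (nondim length^2 / h).
#' @param D_alpha_bar middle-channel chemoattractant diffusivity
#'   (nondim length^2 / h).
#' @param chi_bar middle-channel chemotactic coefficient scale.
#' @param mu_rho reduction factor (> 1) for cell motility and chemotaxis in
#'   the top channel.
#' @param mu_alpha reduction factor (> 1) for chemoattractant diffusivity in
#'   the top channel.
#' @param xi horizontal-loss sink rate (1/h) for cells leaving the imaged
#'   region sideways.
#' @param eta1 macrophage-derived chemoattractant production rate in the
#'   middle channel (conc/h).
#' @param eta2 target-induced chemoattractant release rate per unit PBMC
#'   density in the top channel (conc/(density h)); zero under non-targeting
#'   control conditions.
#' @param kappa chemoattractant uptake rate by PBMCs (1/(density h)).
#' @param nu chemoattractant degradation rate (1/h).
#' @param k receptor-law saturation constant (conc units); must be > 0.
#' @param zeta chemoattractant outflux coefficient at `x = 0`
#'   (1/nondim length).
#' @param rho_tilde constant PBMC source density in the bottom channel.
#' @param x_t channel-interface position in (0, 1); 350 um in physical
#'   coordinates.
#'
#' @return An object of class `infil_params` (a validated named list).
#' @seealso [default_params()] for the shipped study fixtures,
#'   [params_to_json()], [params_from_file()].
#' @export
#' @examples
#' p <- default_params("control")
#' p$eta2   # 0: no target-induced release under control conditions
model_params <- function(D_rho_bar, D_alpha_bar, chi_bar, mu_rho, mu_alpha,
                         xi, eta1, eta2, kappa, nu, k, zeta, rho_tilde, x_t) {
  p <- list(
    D_rho_bar = D_rho_bar, D_alpha_bar = D_alpha_bar, chi_bar = chi_bar,
    mu_rho = mu_rho, mu_alpha = mu_alpha, xi = xi, eta1 = eta1, eta2 = eta2,
    kappa = kappa, nu = nu, k = k, zeta = zeta, rho_tilde = rho_tilde,
    x_t = x_t
  )
  validate_params(p)
}

param_names <- function() {
  c("D_rho_bar", "D_alpha_bar", "chi_bar", "mu_rho", "mu_alpha", "xi",
    "eta1", "eta2", "kappa", "nu", "k", "zeta", "rho_tilde", "x_t")
}

#' Validate a (possibly modified) parameter list
#'
#' Re-checks the invariants of [model_params()] after programmatic edits
#' and restores the `infil_params` class.
#'
#' @param p named list (or `infil_params`) holding every model parameter.
#' @return A validated `infil_params` object.
#' @export
validate_params <- function(p) {
  p <- p[param_names()]
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    stop_domain("non-finite or missing parameter(s): ",
                paste(bad, collapse = ", "))
  nonneg <- c("D_rho_bar", "D_alpha_bar", "chi_bar", "xi", "eta1", "eta2",
              "kappa", "nu", "zeta", "rho_tilde")
  neg <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(neg))
    stop_domain("parameter(s) must be >= 0: ", paste(neg, collapse = ", "))
  if (p$k <= 0) stop_domain("receptor saturation constant k must be > 0")
  if (p$mu_rho <= 1 || p$mu_alpha <= 1)
    stop_domain("mu_rho and mu_alpha must exceed 1 (reduced motility in the top channel)")
  if (p$x_t <= 0 || p$x_t >= 1)
    stop_domain("x_t must lie strictly inside (0, 1)")
  structure(p, class = "infil_params")
}

#' Default ground-truth parameter fixtures
#'
#' Named parameter sets used as synthetic-study ground truths. They are
#' chosen to reproduce the qualitative infiltration phases seen in the
#' microphysiological system: chemotactically driven entry over the first
#' ~24 h, accumulation of the leading cells at the matrix/epithelium
#' interface, and saturation of the total infiltrated count, with
#' per-experiment totals of order a few hundred cells. The `"toxic"` set
#' differs from `"control"` only through a positive target-induced release
#' rate `eta2`, mirroring cytotoxic versus non-targeting antibody
#' conditions.
#'
#' @param condition `"control"` (non-targeting, `eta2 = 0`) or `"toxic"`.
#' @return An `infil_params` object.
#' @export
default_params <- function(condition = c("control", "toxic")) {
  condition <- match.arg(condition)
  p <- model_params(
    D_rho_bar = 2e-3, D_alpha_bar = 0.15, chi_bar = 2,
    mu_rho = 10, mu_alpha = 1e6, xi = 0.08,
    eta1 = 0.7, eta2 = 0, kappa = 5e-4, nu = 2,
    k = 2, zeta = 0.6, rho_tilde = 100, x_t = 0.35
  )
  if (condition == "toxic") p$eta2 <- 0.15
  validate_params(p)
}

#' @export
print.infil_params <- function(x, ...) {
  cat("<infil_params>\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-12s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' Serialise model parameters
#'
#' @param params an `infil_params` object.
#' @param path output file path (`.json` or `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
params_to_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_to_yaml <- function(params, path) {
  yaml::write_yaml(lapply(unclass(params), identity), path)
  invisible(path)
}

#' Read model parameters from a JSON or YAML file
#'
#' @param path file path; format inferred from the extension.
#' @return An `infil_params` object.
#' @export
params_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_params(lapply(as.list(lst), as.numeric))
}
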