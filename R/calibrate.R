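#' Specification of a model fit
#'
#' Declares which model parameters are free, their bounds and scales, the
#' values of the fixed parameters, and the discretisation used when
#' simulating candidate parameter sets. Scale-type parameters (motilities,
#' rates, the saturation constant, the pool density) are best searched in
#' log10 space; geometric/linear parameters (`x_t`, `zeta`) in linear
#' space.
#'
#' @param free named list: one entry per free parameter, each a list with
#'   `lower`, `upper` and optional `log10` flag (default `FALSE`).
#' @param fixed an [model_params()] object supplying every parameter;
#'   entries named in `free` are overridden during fitting.
#' @param roi_length_um physical length of the imaged region mapped onto
#'   the unit interval.
#' @param n_cells finite-volume resolution used in objective evaluations.
#' @param output_times simulation output times (h); must cover the data.
#' @return An object of class `fit_spec`.
#' @export
#' @examples
#' fs <- fit_spec(
#'   free = list(rho_tilde = list(lower = 10, upper = 400, log10 = TRUE),
#'               zeta = list(lower = 0.05, upper = 1)),
#'   fixed = default_params("control"), roi_length_um = 1000)
fit_spec <- function(free, fixed, roi_length_um,
                     n_cells = 200L, output_times = seq(0, 48, by = 2)) {
  stopifnot(inherits(fixed, "infil_params"))
  if (!length(free) || is.null(names(free)) || any(names(free) == ""))
    stop_domain("free must be a named list of parameter descriptors")
  unknown <- setdiff(names(free), param_names())
  if (length(unknown))
    stop_domain("unknown free parameter(s): ", paste(unknown, collapse = ", "))
  free <- lapply(free, function(f) {
    f$log10 <- isTRUE(f$log10)
    if (!is.finite(f$lower) || !is.finite(f$upper) || f$lower >= f$upper)
      stop_domain("free-parameter bounds must be finite with lower < upper")
    if (f$log10 && f$lower <= 0)
      stop_domain("log10-scaled parameters need positive bounds")
    f
  })
  if (roi_length_um <= 0) stop_domain("roi_length_um must be > 0")
  structure(list(free = free, fixed = fixed,
                 roi_length_um = roi_length_um,
                 n_cells = as.integer(n_cells),
                 output_times = as.numeric(output_times)),
            class = "fit_spec")
}

#' Bounds of the free-parameter vector on the optimiser's scale
#'
#' @param spec a [fit_spec()].
#' @return Matrix with rows `lower`, `upper`, one column per free
#'   parameter (log10-transformed where flagged).
#' @export
fit_bounds <- function(spec) {
  lo <- vapply(spec$free, function(f) if (f$log10) log10(f$lower) else f$lower, 0)
  hi <- vapply(spec$free, function(f) if (f$log10) log10(f$upper) else f$upper, 0)
  rbind(lower = lo, upper = hi)
}

#' Assemble a full parameter set from a free-parameter vector
#'
#' @param theta numeric vector on the optimiser's scale, ordered as
#'   `names(spec$free)`.
#' @param spec a [fit_spec()].
#' @return An [model_params()] object.
#' @export
theta_to_params <- function(theta, spec) {
  p <- unclass(spec$fixed)
  nm <- names(spec$free)
  for (i in seq_along(nm)) {
    v <- theta[i]
    if (spec$free[[nm[i]]]$log10) v <- 10^v
    p[[nm[i]]] <- v
  }
  validate_params(p)
}

#' Expected cell counts per spatial bin from a model solution
#'
#' Integrates the PBMC density over each data bin at each requested time:
#' entry (t, b) is \eqn{\int_{bin} \rho(x, t)\,dx}, the model's
#' count-scale prediction for that bin (the density is per unit
#' nondimensional length, so the integral over a bin is a cell count; no
#' extra amplitude factor is needed — the pool density absorbs overall
#' scale). The integral is exact for the finite-volume representation:
#' full cells contribute their cell average times the cell width, partial
#' cells in proportion to their overlap with the bin.
#'
#' @param solution an `infil_solution`.
#' @param bin_edges_um bin edges in um (length `n_bins + 1`).
#' @param roi_length_um physical ROI length mapping positions to \[0, 1\].
#' @param times times (h) at which to evaluate; must be present in the
#'   solution's output times. Default: all solution times.
#' @return Real-valued matrix (times x bins).
#' @export
expected_counts <- function(solution, bin_edges_um, roi_length_um,
                            times = solution$times) {
  ti <- match(times, solution$times)
  if (anyNA(ti))
    stop_domain("requested time(s) absent from the solution: ",
                paste(times[is.na(ti)], collapse = ", "))
  edges <- bin_edges_um / roi_length_um
  if (any(edges < -1e-12) || any(edges > 1 + 1e-12))
    stop_domain("bin edges fall outside the model domain [0, ROI length]")
  edges <- pmin(pmax(edges, 0), 1)
  g <- solution$grid
  # cumulative integral of the piecewise-constant density up to each edge
  cum_at <- function(rho_row) {
    cums <- c(0, cumsum(rho_row) * g$h)
    cell <- pmin(findInterval(edges, g$faces, rightmost.closed = TRUE),
                 g$n_cells)
    cums[cell] + rho_row[cell] * (edges - g$faces[cell])
  }
  out <- t(vapply(ti, function(i) diff(cum_at(solution$rho[i, ])),
                  numeric(length(edges) - 1L)))
  dimnames(out) <- list(time_h = times, bin = seq_len(ncol(out)))
  out
}

#' Sum-of-squares calibration objective
#'
#' Simulates the model at a candidate free-parameter vector and returns
#' the unweighted sum of squared differences between every observed bin
#' count and the corresponding predicted bin integral, summed over all
#' time points. Failed simulations are not propagated as errors: they
#' return a large finite penalty (1000 x the objective of the all-zero
#' prediction) so that surrogate-based optimisation can continue.
#'
#' @param data a `binned_counts` object.
#' @param spec a [fit_spec()] whose `output_times` cover `data$times`.
#' @param theta free-parameter vector on the optimiser's scale.
#' @return Nonnegative scalar; attribute `failed` is `TRUE` for penalty
#'   values.
#' @export
infil_objective <- function(data, spec, theta) {
  b <- fit_bounds(spec)
  if (any(theta < b["lower", ] - 1e-9) || any(theta > b["upper", ] + 1e-9))
    stop_domain("theta outside the fit_spec bounds")
  pred <- try({
    params <- theta_to_params(theta, spec)
    sol <- simulate_infiltration(params, spec$n_cells, spec$output_times)
    expected_counts(sol, data$bin_edges_um, spec$roi_length_um, data$times)
  }, silent = TRUE)
  if (inherits(pred, "try-error")) {
    val <- 1000 * sum(as.numeric(data$counts)^2)
    attr(val, "failed") <- TRUE
    return(val)
  }
  sum((as.numeric(data$counts) - as.numeric(pred))^2)
}
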