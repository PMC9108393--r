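#' Two-parameter objective contour scan
#'
#' Evaluates the calibration objective on a full grid over two free
#' parameters with all other parameters fixed, the tool used to expose
#' practical non-identifiability: a valley (ridge of equally good fits)
#' in the scanned subspace means the data do not constrain the pair,
#' only a combination of them. For the pool density and the outflux
#' coefficient the boundary influx depends on the pair essentially
#' through their product, so the valley follows a reciprocal curve.
#'
#' @param data a `binned_counts` object.
#' @param spec a [fit_spec()] in which both scanned parameters are free.
#' @param pair character vector of the two parameter names to scan.
#' @param ranges list of two `c(min, max)` ranges (natural scale).
#' @param resolution grid points per axis (scalar or length 2, >= 2).
#' @param objective_fn optional replacement objective
#'   `function(value1, value2) -> scalar` (for testing the scan machinery
#'   against analytic landscapes); default uses [infil_objective()].
#' @return An object of class `contour_scan`: list with `pair`, `values1`,
#'   `values2`, `objective` matrix (rows = values of `pair[1]`), and the
#'   fixed-parameter record.
#' @export
contour_scan <- function(data, spec, pair, ranges, resolution = 10,
                         objective_fn = NULL) {
  if (length(pair) != 2L) stop_domain("pair must name exactly two parameters")
  resolution <- rep(as.integer(resolution), length.out = 2L)
  if (any(resolution < 2L)) stop_domain("resolution must be >= 2 per axis")
  if (is.null(objective_fn)) {
    if (!all(pair %in% names(spec$free)))
      stop_domain("both scanned parameters must be free in the fit_spec")
    islog <- vapply(spec$free[pair], function(f) f$log10, TRUE)
    base <- vapply(names(spec$free), function(nm) {
      f <- spec$free[[nm]]
      v <- unclass(spec$fixed)[[nm]]
      if (f$log10) log10(v) else v
    }, 0)
    objective_fn <- function(v1, v2) {
      theta <- base
      theta[pair[1L]] <- if (islog[1L]) log10(v1) else v1
      theta[pair[2L]] <- if (islog[2L]) log10(v2) else v2
      infil_objective(data, spec, theta)
    }
  }
  v1 <- seq(ranges[[1L]][1L], ranges[[1L]][2L], length.out = resolution[1L])
  v2 <- seq(ranges[[2L]][1L], ranges[[2L]][2L], length.out = resolution[2L])
  obj <- matrix(NA_real_, resolution[1L], resolution[2L],
                dimnames = stats::setNames(list(signif(v1, 6), signif(v2, 6)),
                                           pair))
  for (i in seq_along(v1)) for (j in seq_along(v2))
    obj[i, j] <- as.numeric(objective_fn(v1[i], v2[j]))
  if (any(!is.finite(obj))) stop("contour scan produced non-finite entries",
                                 call. = FALSE)
  structure(list(pair = pair, values1 = v1, values2 = v2, objective = obj,
                 fixed = if (!is.null(spec)) spec$fixed else NULL),
            class = "contour_scan")
}

#' @export
print.contour_scan <- function(x, ...) {
  cat(sprintf("<contour_scan> %s x %s, %d x %d grid; objective in [%.3g, %.3g]\n",
              x$pair[1L], x$pair[2L], length(x$values1), length(x$values2),
              min(x$objective), max(x$objective)))
  invisible(x)
}

#' Log-scale view of a scan for display
#'
#' @param scan a `contour_scan`.
#' @param floor lower clip guarding exact zeros before taking log10.
#' @return Matrix of `log10(pmax(objective, floor))`.
#' @export
scan_log10 <- function(scan, floor = 1e-12) {
  log10(pmax(scan$objective, floor))
}

#' Write a contour scan as long-format CSV
#' @param scan a `contour_scan`.
#' @param path output path.
#' @export
write_contour_scan <- function(scan, path) {
  df <- expand.grid(v1 = scan$values1, v2 = scan$values2)
  names(df) <- scan$pair
  df$objective <- as.vector(scan$objective)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Aggregated signed residual map
#'
#' Sums, over a list of fitted experiments, the signed residual
#' (observed count minus model prediction) in every (time, bin) cell.
#' Negative entries mean the model overestimates. Aggregation uses raw
#' sums so that consistently mis-fitted regions accumulate.
#'
#' @param fits list of fits; each element is a list with `data` (a
#'   `binned_counts`) and `solution` (the fitted `infil_solution`).
#' @param roi_length_um ROI length shared by all fits.
#' @return An object of class `residual_map`: list with `times`,
#'   `bin_edges_um`, and the summed `residuals` matrix (times x bins).
#' @export
residual_map <- function(fits, roi_length_um) {
  if (!length(fits)) stop_domain("no fits supplied")
  ref <- fits[[1L]]$data
  acc <- matrix(0, length(ref$times), ncol(ref$counts))
  for (ft in fits) {
    d <- ft$data
    if (!isTRUE(all.equal(d$times, ref$times)) ||
        !isTRUE(all.equal(d$bin_edges_um, ref$bin_edges_um)))
      stop_domain("all fits must share bin edges and times")
    pred <- expected_counts(ft$solution, d$bin_edges_um, roi_length_um,
                            d$times)
    acc <- acc + (d$counts - pred)
  }
  structure(list(times = ref$times, bin_edges_um = ref$bin_edges_um,
                 residuals = acc), class = "residual_map")
}

#' Between-condition count difference surface
#'
#' Aggregates binned counts per condition and returns, for every (time,
#' bin) cell, the targeted-condition total minus the control total —
#' the waterfall view showing when and where the cytotoxic-antibody
#' dynamics diverge from control.
#'
#' @param datasets list of `binned_counts` objects.
#' @param conditions character vector (same length) of condition labels.
#' @param toxic,control labels of the two groups to difference.
#' @return List with `times`, `bin_edges_um` and `difference` matrix
#'   (times x bins; toxic minus control).
#' @export
group_difference <- function(datasets, conditions,
                             toxic = "D66-ESK", control = "DP47") {
  if (length(datasets) != length(conditions))
    stop_domain("datasets and conditions must have equal length")
  pick <- function(label) {
    idx <- which(conditions == label)
    if (!length(idx)) stop_domain("missing condition group: ", label)
    ref <- datasets[[idx[1L]]]
    acc <- matrix(0, length(ref$times), ncol(ref$counts))
    for (i in idx) {
      d <- datasets[[i]]
      if (!isTRUE(all.equal(d$times, ref$times)) ||
          !isTRUE(all.equal(d$bin_edges_um, ref$bin_edges_um)))
        stop_domain("all datasets must share bin edges and times")
      acc <- acc + d$counts
    }
    list(acc = acc, ref = ref)
  }
  tx <- pick(toxic); ct <- pick(control)
  if (!isTRUE(all.equal(tx$ref$times, ct$ref$times)))
    stop_domain("condition groups have mismatched time grids")
  list(times = tx$ref$times, bin_edges_um = tx$ref$bin_edges_um,
       difference = tx$acc - ct$acc)
}
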