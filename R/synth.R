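#' Synthetic study design
#'
#' Describes an in-silico version of the infiltration study: paired
#' control / targeted-antibody condition groups, regular imaging of each
#' well, a region of interest spanning the matrix and epithelium
#' channels with the interface at 350 um, and ground-truth model
#' parameters per condition. The generator built on this design
#' produces particle tables with the same structure as the image
#' analysis exports, so the whole quantification-calibration pipeline is
#' testable without the original raw data.
#'
#' @param n_control,n_toxic experiments per condition (default 8 + 8).
#' @param interval_h imaging interval in hours (default 2).
#' @param horizon_h last imaging time (default 48; must be a multiple of
#'   `interval_h`).
#' @param roi_length_um imaged region length (default 1000 um).
#' @param interface_um matrix/epithelium interface position (default
#'   350 um; mapped to the model's `x_t`).
#' @param params_control,params_toxic ground-truth [model_params()] per
#'   condition (defaults: [default_params()] fixtures; the interface is
#'   forced to `interface_um / roi_length_um`).
#' @param noise `"poisson"` (independent Poisson count per time and bin)
#'   or `"none"` (rounded expected counts).
#' @param n_bins spatial bins used to place cells (default 20).
#' @param n_cells finite-volume resolution of the ground-truth solve.
#' @param area_meanlog,area_sdlog lognormal singleton-area model
#'   (defaults: median 40 um^2, sdlog 0.25).
#' @param clump_prob probability that a generated cell is merged into a
#'   clump with a neighbour (areas add), exercising declumping.
#' @param seed master seed; per-experiment seeds are derived from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_control = 8L, n_toxic = 8L, interval_h = 2,
                         horizon_h = 48, roi_length_um = 1000,
                         interface_um = 350,
                         params_control = default_params("control"),
                         params_toxic = default_params("toxic"),
                         noise = c("poisson", "none"), n_bins = 20L,
                         n_cells = 200L, area_meanlog = log(40),
                         area_sdlog = 0.25, clump_prob = 0.1, seed = 1L) {
  noise <- match.arg(noise)
  if (n_control < 1L || n_toxic < 1L)
    stop_domain("need at least one experiment per condition")
  if (horizon_h %% interval_h != 0)
    stop_domain("horizon_h must be a multiple of interval_h")
  if (interface_um <= 0 || interface_um >= roi_length_um)
    stop_domain("interface must lie inside the ROI")
  xt <- interface_um / roi_length_um
  params_control$x_t <- xt
  params_toxic$x_t <- xt
  structure(list(
    n_control = as.integer(n_control), n_toxic = as.integer(n_toxic),
    interval_h = interval_h, horizon_h = horizon_h,
    times = seq(0, horizon_h, by = interval_h),
    roi_length_um = roi_length_um, interface_um = interface_um,
    params_control = validate_params(params_control),
    params_toxic = validate_params(params_toxic),
    noise = noise, n_bins = as.integer(n_bins),
    n_cells = as.integer(n_cells),
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    clump_prob = clump_prob, seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d control + %d toxic wells; t = 0..%g h by %g h; ROI %g um (interface %g um); %s noise\n",
    x$n_control, x$n_toxic, x$horizon_h, x$interval_h, x$roi_length_um,
    x$interface_um, x$noise))
  invisible(x)
}

design_params <- function(design, condition) {
  switch(condition,
         DP47 = design$params_control,
         `D66-ESK` = design$params_toxic,
         stop_domain("condition not defined in the design: ", condition))
}

#' Ground-truth expected bin counts for a design condition
#'
#' Simulates the PDE at the condition's ground-truth parameters and
#' integrates the density over the design's bins: the Poisson means of
#' the generator.
#'
#' @param design a [study_design()].
#' @param condition `"DP47"` (control) or `"D66-ESK"` (toxic).
#' @return List with `expected` matrix (times x bins), `bin_edges_um`,
#'   `times`, and the underlying `solution`.
#' @export
design_expected_counts <- function(design, condition) {
  params <- design_params(design, condition)
  sol <- simulate_infiltration(params, design$n_cells, design$times)
  edges <- seq(0, design$roi_length_um, length.out = design$n_bins + 1L)
  list(expected = expected_counts(sol, edges, design$roi_length_um),
       bin_edges_um = edges, times = design$times, solution = sol)
}

#' Generate one synthetic experiment
#'
#' Draws a particle table for a single well: per (time, bin) a cell
#' count (Poisson around the model's expected count, or its half-up
#' rounding in noise-free mode), uniform cell positions within the bin,
#' and segmentation-like areas. In Poisson mode each cell is
#' independently merged into a clump with a same-bin neighbour with
#' probability `clump_prob` (areas adding), so downstream declumping is
#' exercised; noise-free mode emits constant-area singletons so that
#' binning and declumping invert the generator exactly.
#'
#' @param design a [study_design()].
#' @param condition `"DP47"` or `"D66-ESK"`.
#' @param seed experiment seed.
#' @param experiment_id id string recorded in the table.
#' @param expected optional precomputed [design_expected_counts()] for
#'   this condition (avoids re-solving the PDE across many replicates).
#' @return A particle table data frame.
#' @export
generate_experiment <- function(design, condition, seed,
                                experiment_id = paste0(condition, "_1"),
                                expected = NULL) {
  if (is.null(expected)) expected <- design_expected_counts(design, condition)
  lam <- expected$expected
  edges <- expected$bin_edges_um
  with_seed(seed, {
    rows <- list()
    for (ti in seq_along(expected$times)) {
      for (b in seq_len(ncol(lam))) {
        n <- if (design$noise == "poisson") stats::rpois(1L, lam[ti, b])
             else as.integer(round_half_up(lam[ti, b]))
        if (n < 1L) next
        pos <- stats::runif(n, edges[b], edges[b + 1L])
        if (design$noise == "none") {
          area <- rep(40, n)
          grp <- seq_len(n)
        } else {
          area <- stats::rlnorm(n, design$area_meanlog, design$area_sdlog)
          grp <- seq_len(n)
          merge_me <- which(stats::runif(n) < design$clump_prob)
          for (i in merge_me) {
            if (n < 2L) break
            partner <- sample(setdiff(seq_len(n), i), 1L)
            grp[grp == grp[i]] <- grp[partner]
          }
        }
        agg_area <- tapply(area, grp, sum)
        agg_pos <- tapply(pos, grp, function(z) z[1L])
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = experiment_id, condition = condition,
          time_h = expected$times[ti],
          x_um = as.numeric(agg_pos), area_um2 = as.numeric(agg_area))
      }
    }
    tb <- if (length(rows)) do.call(rbind, rows)
          else data.frame(experiment_id = character(), condition = character(),
                          time_h = numeric(), x_um = numeric(),
                          area_um2 = numeric())
    rownames(tb) <- NULL
    tb
  })
}

#' Generate a full synthetic dataset
#'
#' One particle table per experiment (control wells use the control
#' ground truth with no target-induced release, targeted wells the toxic
#' ground truth), with per-experiment seeds derived from the design's
#' master seed. Also returns per-experiment binned counts.
#'
#' @param design a [study_design()].
#' @return List with `table` (all experiments pooled), `binned` (list of
#'   per-experiment `binned_counts`), `conditions` (label per
#'   experiment), and `expected` (per-condition ground truth from
#'   [design_expected_counts()]).
#' @export
generate_dataset <- function(design) {
  conds <- c(rep("DP47", design$n_control),
             rep("D66-ESK", design$n_toxic))
  ids <- paste0(ifelse(conds == "DP47", "ctrl_", "tox_"),
                c(seq_len(design$n_control), seq_len(design$n_toxic)))
  seeds <- derive_seeds(design$seed, length(conds))
  expected <- list(
    `DP47` = design_expected_counts(design, "DP47"),
    `D66-ESK` = design_expected_counts(design, "D66-ESK"))
  tables <- lapply(seq_along(conds), function(i)
    generate_experiment(design, conds[i], seeds[i], ids[i],
                        expected = expected[[conds[i]]]))
  binned <- lapply(tables, function(tb)
    bin_counts_on_schedule(tb, design))
  list(table = do.call(rbind, tables), binned = binned,
       conditions = conds, ids = ids, expected = expected)
}

# bin_counts, but guaranteeing every design time appears even if a table
# has no particles at that time (early frames are often empty).
bin_counts_on_schedule <- function(table, design) {
  bc <- bin_counts(table, design$roi_length_um, design$n_bins)
  miss <- setdiff(design$times, bc$times)
  if (length(miss)) {
    counts <- matrix(0L, length(design$times), design$n_bins)
    counts[match(bc$times, design$times), ] <- bc$counts
    bc$times <- design$times
    bc$counts <- counts
    bc$totals <- as.integer(rowSums(counts))
  }
  bc
}
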