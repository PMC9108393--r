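# Configuration-driven pipeline entry points. Each run_* function takes a
# config (YAML/JSON path or an equivalent named list), writes its
# artifacts plus a manifest (config hash, seed, package version) into the
# config's output directory, and returns the written paths invisibly.

#' Read a run configuration
#'
#' @param config path to a YAML or JSON file, or a named list used as-is.
#' @return Named list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_domain("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") jsonlite::read_json(config,
                                                     simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_domain("config must be a file path or a list")
  config
}

run_setup <- function(config, default_seed = 1L) {
  config <- read_run_config(config)
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_domain("cannot create output directory: ", out_dir)
  config$seed <- as.integer(config$seed %||% default_seed)
  list(config = config, out_dir = out_dir)
}

write_manifest <- function(config, out_dir, artifact_paths) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("infilsim")),
    artifacts = artifact_paths,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

config_params <- function(config) {
  if (!is.null(config$params_file)) return(params_from_file(config$params_file))
  if (!is.null(config$params))
    return(validate_params(lapply(config$params, as.numeric)))
  if (!is.null(config$condition)) return(default_params(config$condition))
  stop_domain("config must provide params, params_file, or condition")
}

#' Run a forward simulation from a config
#'
#' Config keys: `params` (named list) / `params_file` / `condition`;
#' `n_cells` (default 200); `times` or `horizon_h` + `interval_h`;
#' `output_dir`; `seed`. Writes `solution.csv` (long format),
#' `summary.json` (totals, boundary-flux quadrature, mass budget) and
#' `manifest.json`.
#'
#' @param config path or list (see [read_run_config()]).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config) {
  s <- run_setup(config)
  config <- s$config
  params <- config_params(config)
  times <- if (!is.null(config$times)) as.numeric(config$times)
           else seq(0, config$horizon_h %||% 48,
                    by = config$interval_h %||% 2)
  sol <- simulate_infiltration(params, as.integer(config$n_cells %||% 200L),
                               times)
  sol_path <- file.path(s$out_dir, "solution.csv")
  write_solution_csv(sol, sol_path)
  influx_int <- trapz(sol$times, sol$influx_record)
  nT <- length(sol$times)
  summary <- list(
    final_total_cells = sol$total_cells[nT],
    influx_time_integral = influx_int,
    mass_budget_gap = influx_int - sol$total_cells[nT] -
      params$xi * trapz(sol$times, sol$total_cells),
    alpha_outflux_final = sol$alpha_outflux_record[nT],
    seed = config$seed
  )
  sum_path <- file.path(s$out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA)
  paths <- list(solution = sol_path, summary = sum_path)
  paths$manifest <- write_manifest(config, s$out_dir, paths)
  invisible(paths)
}

config_design <- function(config) {
  dz <- config$design %||% list()
  args <- list()
  for (nm in c("n_control", "n_toxic", "interval_h", "horizon_h",
               "roi_length_um", "interface_um", "noise", "n_bins",
               "n_cells", "clump_prob"))
    if (!is.null(dz[[nm]])) args[[nm]] <- dz[[nm]]
  if (!is.null(dz$params_control))
    args$params_control <- validate_params(lapply(dz$params_control, as.numeric))
  if (!is.null(dz$params_toxic))
    args$params_toxic <- validate_params(lapply(dz$params_toxic, as.numeric))
  args$seed <- config$seed
  do.call(study_design, args)
}

#' Generate a synthetic dataset from a config
#'
#' Config keys: `design` (a named list of [study_design()] arguments),
#' `output_dir`, `seed`. Writes `particles.csv`, per-experiment
#' `counts_<id>.csv`, and `manifest.json`.
#'
#' @param config path or list.
#' @return Invisibly, the written paths.
#' @export
run_synth <- function(config) {
  s <- run_setup(config)
  config <- s$config
  design <- config_design(config)
  ds <- generate_dataset(design)
  part_path <- file.path(s$out_dir, "particles.csv")
  write_particle_table(ds$table, part_path)
  count_paths <- vapply(seq_along(ds$binned), function(i) {
    p <- file.path(s$out_dir, paste0("counts_", ds$ids[i], ".csv"))
    write_binned_counts(ds$binned[[i]], p)
    p
  }, "")
  paths <- list(particles = part_path, counts = as.list(count_paths))
  paths$manifest <- write_manifest(config, s$out_dir, paths)
  invisible(paths)
}

#' Quantify a particle table from a config
#'
#' Config keys: `particles_file`, `roi_length_um`, `n_bins` (default 20),
#' `summary_time_h` (default: the last imaged time), `output_dir`,
#' `seed`. Writes pooled-per-condition `counts_<condition>.csv`,
#' `summary.csv` (per-condition totals and distances) and
#' `manifest.json`.
#'
#' @param config path or list.
#' @return Invisibly, the written paths.
#' @export
run_quantify <- function(config) {
  s <- run_setup(config)
  config <- s$config
  if (is.null(config$particles_file))
    stop_domain("config must name particles_file")
  tb <- read_particle_table(config$particles_file)
  roi <- as.numeric(config$roi_length_um %||%
                      stop_domain("config must give roi_length_um"))
  nb <- as.integer(config$n_bins %||% 20L)
  paths <- list()
  for (cc in unique(tb$condition)) {
    bc <- bin_counts(tb[tb$condition == cc, , drop = FALSE], roi, nb)
    p <- file.path(s$out_dir,
                   paste0("counts_", gsub("[^A-Za-z0-9]", "_", cc), ".csv"))
    write_binned_counts(bc, p)
    paths[[paste0("counts_", cc)]] <- p
  }
  t_sum <- as.numeric(config$summary_time_h %||% max(tb$time_h))
  sm <- summarize_infiltration(tb, t_sum)
  sum_path <- file.path(s$out_dir, "summary.csv")
  utils::write.csv(sm, sum_path, row.names = FALSE)
  paths$summary <- sum_path
  paths$manifest <- write_manifest(config, s$out_dir, paths)
  invisible(paths)
}

config_fit_spec <- function(config) {
  fs <- config$fit_spec %||% stop_domain("config must contain fit_spec")
  fixed <- if (!is.null(fs$fixed_file)) params_from_file(fs$fixed_file)
           else if (!is.null(fs$fixed))
             validate_params(lapply(fs$fixed, as.numeric))
           else default_params(fs$condition %||% "control")
  fit_spec(free = fs$free, fixed = fixed,
           roi_length_um = as.numeric(fs$roi_length_um),
           n_cells = as.integer(fs$n_cells %||% 200L),
           output_times = as.numeric(fs$output_times %||% seq(0, 48, by = 2)))
}

#' Fit the model to binned counts from a config
#'
#' Config keys: `counts_file` (written by [write_binned_counts()]),
#' `fit_spec` (`free`, plus `fixed`/`fixed_file`/`condition`,
#' `roi_length_um`, `n_cells`, `output_times`), `optimiser` (`budget`,
#' `q`, optional `n_init`), `output_dir`, `seed`. Writes `fit.json`
#' (incumbent, bounds, termination), `history.csv` and `manifest.json`.
#'
#' @param config path or list.
#' @return Invisibly, the written paths.
#' @export
run_fit <- function(config) {
  s <- run_setup(config)
  config <- s$config
  if (is.null(config$counts_file)) stop_domain("config must name counts_file")
  if (!file.exists(config$counts_file))
    stop_domain("counts file not found: ", config$counts_file)
  data <- read_binned_counts(config$counts_file)
  spec <- config_fit_spec(config)
  opt <- config$optimiser %||% list()
  budget <- as.integer(opt$budget %||% 200L)
  n_init <- if (!is.null(opt$n_init)) as.integer(opt$n_init) else NULL
  res <- fit_infiltration(data, spec, budget = budget,
                          q = as.integer(opt$q %||% 4L),
                          seed = config$seed, n_init = n_init)
  fit_path <- file.path(s$out_dir, "fit.json")
  jsonlite::write_json(list(
    incumbent = as.list(res$par_natural), objective = res$value,
    n_eval = res$n_eval, termination = res$termination,
    bounds_final = as.data.frame(res$bounds_final), seed = res$seed
  ), fit_path, auto_unbox = TRUE, digits = NA)
  hist_path <- file.path(s$out_dir, "history.csv")
  utils::write.csv(res$history, hist_path, row.names = FALSE)
  paths <- list(fit = fit_path, history = hist_path)
  paths$manifest <- write_manifest(config, s$out_dir, paths)
  invisible(paths)
}

#' Contour-scan a parameter pair from a config
#'
#' Config keys: `counts_file`, `fit_spec` (both scanned parameters
#' free), `scan` (`pair`, `ranges`, `resolution`), `output_dir`, `seed`.
#' Writes `scan.csv` and `manifest.json`.
#'
#' @param config path or list.
#' @return Invisibly, the written paths.
#' @export
run_scan <- function(config) {
  s <- run_setup(config)
  config <- s$config
  data <- read_binned_counts(config$counts_file %||%
                               stop_domain("config must name counts_file"))
  spec <- config_fit_spec(config)
  sc <- config$scan %||% stop_domain("config must contain scan")
  scan <- contour_scan(data, spec, pair = unlist(sc$pair),
                       ranges = lapply(sc$ranges, as.numeric),
                       resolution = sc$resolution %||% 10)
  scan_path <- file.path(s$out_dir, "scan.csv")
  write_contour_scan(scan, scan_path)
  paths <- list(scan = scan_path)
  paths$manifest <- write_manifest(config, s$out_dir, paths)
  invisible(paths)
}
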