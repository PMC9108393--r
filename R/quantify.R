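#' Convert a segmented-particle area into a cell count (declumping)
#'
#' Watershed segmentation of crowded fields occasionally fails to separate
#' touching cells, leaving one region where several cells sit. The
#' declumping rule converts a region's area into a cell count by rounding
#' `area / 50` to the nearest multiple (half up), never below one cell.
#' The 50 um^2 threshold reflects a typical PBMC diameter under 10 um, so
#' any region above 75 um^2 is treated as more than one cell.
#'
#' @param area_um2 vector of region areas in um^2 (strictly positive).
#' @param threshold_um2 single-cell threshold area (default 50 um^2).
#' @return Integer vector of cell counts (>= 1).
#' @export
#' @examples
#' declump(c(30, 74, 76, 120, 130))  # 1 1 2 2 3
declump <- function(area_um2, threshold_um2 = 50) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stop_domain("areas must be finite and > 0")
  as.integer(pmax(1, round_half_up(area_um2 / threshold_um2)))
}

#' Validate a particle table
#'
#' A particle table holds one row per segmented region as exported by the
#' upstream image analysis: columns `experiment_id`, `condition`,
#' `time_h`, `x_um` (position along the infiltration axis measured from
#' the bottom-channel interface) and `area_um2`.
#'
#' @param table data frame of particle records.
#' @param roi_length_um imaged region length; positions must not exceed it.
#' @return The table, invisibly, after validation.
#' @export
validate_particle_table <- function(table, roi_length_um = NULL) {
  need <- c("experiment_id", "condition", "time_h", "x_um", "area_um2")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_domain("particle table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(table)) {
    if (any(!is.finite(table$area_um2)) || any(table$area_um2 <= 0))
      stop_domain("particle areas must be finite and > 0")
    if (any(!is.finite(table$x_um)) || any(table$x_um < 0))
      stop_domain("particle positions must be finite and >= 0")
    if (!is.null(roi_length_um) && any(table$x_um > roi_length_um)) {
      bad <- which(table$x_um > roi_length_um)
      stop_domain("position(s) outside the ROI (length ", roi_length_um,
                  " um) in row(s): ",
                  paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  invisible(table)
}

#' Read / write particle tables as CSV
#'
#' @param path file path.
#' @return `read_particle_table`: the validated data frame.
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop_domain("particle file not found: ", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_particle_table(tb)
  tb
}

#' @rdname read_particle_table
#' @param table particle table data frame.
#' @export
write_particle_table <- function(table, path) {
  validate_particle_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Bin declumped cell counts over space and time
#'
#' Partitions the region of interest into `n_bins` equal-width bins
#' (half-open `[a, b)`, last bin closed) and counts declumped cells per
#' imaging time and bin. Each particle contributes `declump(area)` cells
#' to the bin containing its position.
#'
#' @param table particle table (see [validate_particle_table()]); may pool
#'   several experiments — counts are summed over whatever the table holds.
#' @param roi_length_um length of the imaged region in um.
#' @param n_bins number of spatial bins (default 20).
#' @return An object of class `binned_counts`: list with `times`,
#'   `bin_edges_um` (length `n_bins + 1`), integer `counts` matrix
#'   (times x bins) and `totals` (declumped total per time).
#' @export
bin_counts <- function(table, roi_length_um, n_bins = 20L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop_domain("n_bins must be >= 1")
  validate_particle_table(table, roi_length_um)
  times <- sort(unique(table$time_h))
  edges <- seq(0, roi_length_um, length.out = n_bins + 1L)
  counts <- matrix(0L, nrow = length(times), ncol = n_bins,
                   dimnames = list(time_h = times, bin = seq_len(n_bins)))
  if (nrow(table)) {
    cells <- declump(table$area_um2)
    # half-open bins [a, b); the right boundary of the last bin is closed
    bin <- pmin(findInterval(table$x_um, edges, rightmost.closed = TRUE),
                n_bins)
    ti <- match(table$time_h, times)
    for (r in seq_len(nrow(table)))
      counts[ti[r], bin[r]] <- counts[ti[r], bin[r]] + cells[r]
  }
  structure(list(times = times, bin_edges_um = edges, counts = counts,
                 totals = as.integer(rowSums(counts))),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %d times x %d bins (ROI %g um); final total %d cells\n",
              length(x$times), ncol(x$counts), max(x$bin_edges_um),
              x$totals[length(x$totals)]))
  invisible(x)
}

#' Write binned counts as long-format CSV
#'
#' Columns: `time_h`, `bin_index`, `bin_left_um`, `bin_right_um`, `count`.
#' @param bc a `binned_counts` object.
#' @param path output path.
#' @export
write_binned_counts <- function(bc, path) {
  nb <- ncol(bc$counts)
  df <- data.frame(
    time_h = rep(bc$times, each = nb),
    bin_index = rep(seq_len(nb), times = length(bc$times)),
    bin_left_um = rep(bc$bin_edges_um[-(nb + 1L)], times = length(bc$times)),
    bin_right_um = rep(bc$bin_edges_um[-1L], times = length(bc$times)),
    count = as.vector(t(bc$counts))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read binned counts from long-format CSV
#' @param path file written by [write_binned_counts()].
#' @return A `binned_counts` object.
#' @export
read_binned_counts <- function(path) {
  if (!file.exists(path)) stop_domain("counts file not found: ", path)
  df <- utils::read.csv(path)
  times <- sort(unique(df$time_h))
  bins <- sort(unique(df$bin_index))
  edges <- c(df$bin_left_um[match(bins, df$bin_index)],
             max(df$bin_right_um))
  counts <- matrix(0L, length(times), length(bins))
  counts[cbind(match(df$time_h, times), match(df$bin_index, bins))] <-
    as.integer(df$count)
  structure(list(times = times, bin_edges_um = edges, counts = counts,
                 totals = as.integer(rowSums(counts))),
            class = "binned_counts")
}

#' Per-condition infiltration summaries at a fixed time
#'
#' For each condition at `at_time_h`: the mean declumped cell total per
#' experiment, and the mean distance travelled per cell (the recorded
#' position from the bottom-channel interface, pooling all cells in the
#' condition with each particle weighted by its declumped count).
#'
#' @param table particle table covering one or more experiments.
#' @param at_time_h imaging time at which to summarise (must be present).
#' @return Data frame with one row per condition: `condition`,
#'   `n_experiments`, `mean_total_cells`, `mean_distance_um` (`NA` with a
#'   warning for empty condition groups).
#' @export
summarize_infiltration <- function(table, at_time_h) {
  validate_particle_table(table)
  tb <- table[table$time_h == at_time_h, , drop = FALSE]
  if (!nrow(tb))
    stop_domain("time ", at_time_h, " h not present in the particle table")
  conds <- unique(table$condition)
  out <- lapply(conds, function(cc) {
    sub <- tb[tb$condition == cc, , drop = FALSE]
    if (!nrow(sub)) {
      warning("condition '", cc, "' has no particles at ", at_time_h,
              " h; statistics undefined", call. = FALSE)
      return(data.frame(condition = cc, n_experiments = 0L,
                        mean_total_cells = NA_real_,
                        mean_distance_um = NA_real_))
    }
    cells <- declump(sub$area_um2)
    totals <- tapply(cells, sub$experiment_id, sum)
    data.frame(condition = cc, n_experiments = length(totals),
               mean_total_cells = mean(totals),
               mean_distance_um = sum(cells * sub$x_um) / sum(cells))
  })
  do.call(rbind, out)
}
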