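#' Fill missing days by monotone piecewise cubic interpolation
#'
#' Interpolates each taxon's trajectory onto the full integer day grid
#' `min(day)..max(day)` with the shape-preserving PCHIP scheme: observed
#' days are reproduced exactly, monotone segments stay monotone, values
#' never overshoot the bracketing observations, and non-negative input stays
#' non-negative. Interpolated fraction columns are renormalized to unit sum
#' unless `renormalize = FALSE`.
#'
#' @param table An `otu_table` with fractional units and >= 4 samples.
#' @param renormalize Renormalize interpolated columns to sum to 1
#'   (default `TRUE`); only applies to fractional tables.
#' @return An `otu_table` with one sample per day.
#' @export
fill_missing_days <- function(table, renormalize = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  if (n_samples(table) < 4) stop("need at least 4 observed days to interpolate")
  days <- round(table$sample_days)
  if (anyDuplicated(days)) {
    stop("duplicate days after rounding to the integer grid: day ",
         days[duplicated(days)][[1]])
  }
  grid <- seq(min(days), max(days))
  if (length(grid) == length(days)) return(table)
  vals <- t(apply(table$values, 1, function(y) pracma::pchip(days, y, grid)))
  vals[vals < 0] <- 0   # guard against sub-eps negatives
  if (table$units == "fractions" && renormalize) {
    cs <- colSums(vals)
    if (any(cs == 0)) stop("interpolation produced an all-zero column")
    vals <- sweep(vals, 2, cs, "/")
  }
  ids <- paste0("d", grid)
  obs <- match(days, grid)
  ids[obs] <- table$sample_ids
  if (table$units == "fractions" && !renormalize) {
    # interpolated compositions do not close exactly; keep them as-is
    new_otu_table(vals, table$taxon_ids, grid, ids, units = table$units,
                  taxonomy = table$taxonomy)
  } else {
    otu_table(vals, table$taxon_ids, grid, ids, units = table$units,
              taxonomy = table$taxonomy)
  }
}

#' First-difference an OTU table into a rate matrix
#'
#' Row `r` of the result is `column(r+1) - column(r)`: the per-day abundance
#' change of each taxon. For fractional input every row sums to zero
#' (differences of compositions).
#'
#' @param table An `otu_table` with >= 2 samples on a gap-free daily grid
#'   (a warning is issued otherwise).
#' @return A [rate_matrix()] with `m - 1` rows.
#' @export
first_difference <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  m <- n_samples(table)
  if (m < 2) stop("need at least 2 samples to difference")
  gaps <- diff(table$sample_days)
  if (any(abs(gaps - 1) > 1e-8)) {
    warning("sample days are not a gap-free daily grid; differences span unequal intervals")
  }
  rate_matrix(t(table$values)[-1, , drop = FALSE] - t(table$values)[-m, , drop = FALSE],
              table$taxon_ids,
              day_from = table$sample_days[-m], day_to = table$sample_days[-1],
              source_units = table$units)
}
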