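#' Construct an OTU time-series table
#'
#' The package's central container: an `n` taxa by `m` samples abundance
#' matrix with per-sample collection days. Values are either raw read counts
#' or relative abundances (fractions), flagged by the `units` tag. Samples
#' are always kept in increasing day order.
#'
#' @param values Numeric matrix, taxa in rows, samples in columns. No
#'   negative entries. If `units = "fractions"` every column must sum to 1.
#' @param taxon_ids Character vector of unique taxon identifiers, one per row.
#' @param sample_days Numeric vector of collection days, one per column;
#'   duplicates are an error. Columns are reordered so days increase.
#' @param sample_ids Optional character vector of sample identifiers; defaults
#'   to `"d<day>"`.
#' @param units `"counts"` or `"fractions"`.
#' @param taxonomy Optional character vector of lineage strings, one per taxon.
#'
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(values, taxon_ids, sample_days,
                      sample_ids = NULL, units = c("counts", "fractions"),
                      taxonomy = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (anyNA(values)) stop("`values` contains missing entries")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative abundance at taxon row %d, sample column %d",
                 neg[1, 1], neg[1, 2]))
  }
  taxon_ids <- as.character(taxon_ids)
  if (length(taxon_ids) != nrow(values)) {
    stop("length(taxon_ids) must equal nrow(values)")
  }
  dup <- taxon_ids[duplicated(taxon_ids)]
  if (length(dup) > 0) stop("duplicated taxon id: ", dup[[1]])
  sample_days <- as.numeric(sample_days)
  if (length(sample_days) != ncol(values)) {
    stop("length(sample_days) must equal ncol(values)")
  }
  if (anyNA(sample_days)) stop("sample_days contains missing values")
  if (anyDuplicated(sample_days)) {
    stop("duplicate sample day: ", sample_days[duplicated(sample_days)][[1]])
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("d", format(sample_days, trim = TRUE, scientific = FALSE))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)")
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != nrow(values)) {
      stop("length(taxonomy) must equal nrow(values)")
    }
  }
  ord <- order(sample_days)
  values <- values[, ord, drop = FALSE]
  sample_days <- sample_days[ord]
  sample_ids <- sample_ids[ord]
  if (units == "fractions") {
    cs <- colSums(values)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad) > 0) {
      stop("fractional column does not sum to 1: sample ", sample_ids[bad[[1]]])
    }
  }
  dimnames(values) <- list(taxon_ids, sample_ids)
  structure(
    list(values = values, taxon_ids = taxon_ids, taxonomy = taxonomy,
         sample_days = sample_days, sample_ids = sample_ids, units = units),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d taxa x %d samples (%s), days %s..%s\n",
              n_taxa(x), n_samples(x), x$units,
              format(min(x$sample_days)), format(max(x$sample_days))))
  invisible(x)
}

#' Number of taxa / samples in an `otu_table`
#' @param x An `otu_table`.
#' @return Integer scalar.
#' @export
n_taxa <- function(x) nrow(x$values)

#' @rdname n_taxa
#' @export
n_samples <- function(x) ncol(x$values)

#' @exportS3Method tibble::as_tibble
as_tibble.otu_table <- function(x, ...) {
  out <- tibble::tibble(
    taxon_id = rep(x$taxon_ids, times = n_samples(x)),
    sample_id = rep(x$sample_ids, each = n_taxa(x)),
    day = rep(x$sample_days, each = n_taxa(x)),
    abundance = as.vector(x$values)
  )
  if (!is.null(x$taxonomy)) {
    out$taxonomy <- rep(x$taxonomy, times = n_samples(x))
  }
  out
}

#' Restrict an OTU table to a window of days
#'
#' Keeps samples with `from <= day <= to`. Used to excise perturbed windows
#' (e.g. travel or food-poisoning episodes) before model fitting.
#'
#' @param table An `otu_table`.
#' @param from,to Day bounds (inclusive); `NULL` leaves that side open.
#' @return An `otu_table` with the retained samples.
#' @export
slice_days <- function(table, from = NULL, to = NULL) {
  stopifnot(inherits(table, "otu_table"))
  keep <- rep(TRUE, n_samples(table))
  if (!is.null(from)) keep <- keep & table$sample_days >= from
  if (!is.null(to)) keep <- keep & table$sample_days <= to
  if (!any(keep)) stop("day window retains no samples")
  subset_samples_idx(table, which(keep))
}

# internal: subset by sample index, preserving metadata
subset_samples_idx <- function(table, idx) {
  otu_table(table$values[, idx, drop = FALSE], table$taxon_ids,
            table$sample_days[idx], table$sample_ids[idx],
            units = table$units, taxonomy = table$taxonomy)
}

# internal: subset by taxon index. A taxon-filtered fractional table keeps
# relative abundances of the FULL community, so its columns need not close
# to 1; bypass the unit-sum check.
subset_taxa_idx <- function(table, idx) {
  new_otu_table(table$values[idx, , drop = FALSE], table$taxon_ids[idx],
                table$sample_days, table$sample_ids,
                units = table$units,
                taxonomy = if (is.null(table$taxonomy)) NULL else table$taxonomy[idx])
}

# internal constructor without the fractional unit-sum invariant, for
# taxon-filtered and unrenormalized interpolated tables
new_otu_table <- function(values, taxon_ids, sample_days, sample_ids,
                          units, taxonomy = NULL) {
  ord <- order(sample_days)
  values <- as.matrix(values)[, ord, drop = FALSE]
  dimnames(values) <- list(taxon_ids, sample_ids[ord])
  structure(
    list(values = values, taxon_ids = as.character(taxon_ids),
         taxonomy = taxonomy, sample_days = as.numeric(sample_days)[ord],
         sample_ids = as.character(sample_ids)[ord], units = units),
    class = "otu_table"
  )
}

#' Construct a rate matrix (first-difference container)
#'
#' Rows are day-to-day changes (interval `t -> t+1`), columns are taxa.
#' Produced by [first_difference()]; consumed by the sVAR fitter.
#'
#' @param values Numeric matrix, `m - 1` intervals x `n` taxa.
#' @param taxon_ids Character vector of taxon identifiers.
#' @param day_from,day_to Numeric vectors labelling each interval's endpoints.
#' @param source_units Units of the differenced table.
#' @return An object of class `rate_matrix`.
#' @export
rate_matrix <- function(values, taxon_ids, day_from, day_to,
                        source_units = "fractions") {
  values <- as.matrix(values)
  stopifnot(length(taxon_ids) == ncol(values),
            length(day_from) == nrow(values),
            length(day_to) == nrow(values))
  dimnames(values) <- list(NULL, taxon_ids)
  structure(
    list(values = values, taxon_ids = as.character(taxon_ids),
         day_from = as.numeric(day_from), day_to = as.numeric(day_to),
         source_units = source_units),
    class = "rate_matrix"
  )
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %d intervals x %d taxa (source: %s)\n",
              nrow(x$values), ncol(x$values), x$source_units))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.rate_matrix <- function(x, ...) {
  tibble::tibble(
    taxon_id = rep(x$taxon_ids, each = nrow(x$values)),
    day_from = rep(x$day_from, times = ncol(x$values)),
    day_to = rep(x$day_to, times = ncol(x$values)),
    rate = as.vector(x$values)
  )
}
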