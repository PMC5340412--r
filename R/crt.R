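#' Sarle's bimodality coefficient
#'
#' Sample-corrected form `b = (g3^2 + 1) / (g4 + 3(m-1)^2 / ((m-2)(m-3)))`
#' with `g3` the sample skewness (G1) and `g4` the sample excess kurtosis
#' (G2). Limits: 1/3 for a normal population, 5/9 for a uniform, 1 for a
#' symmetric two-point (Bernoulli) distribution. Values above ~5/9 suggest
#' bimodality. Scale-invariant. Set `sample_corrected = FALSE` for the
#' population-moment variant.
#'
#' @param series Numeric vector, length >= 4, nonzero variance.
#' @param sample_corrected Use bias-corrected skewness/kurtosis (default TRUE).
#' @return The coefficient `b`.
#' @export
bimodality <- function(series, sample_corrected = TRUE) {
  x <- as.numeric(series)
  m <- length(x)
  if (m < 4) stop("need at least 4 observations")
  if (stats::var(x) == 0) stop("bimodality undefined for a constant series")
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  b1 <- m3 / m2^1.5          # population skewness
  b2 <- m4 / m2^2 - 3        # population excess kurtosis
  if (sample_corrected) {
    g3 <- b1 * sqrt(m * (m - 1)) / (m - 2)
    g4 <- ((m + 1) * b2 + 6) * (m - 1) / ((m - 2) * (m - 3))
    (g3^2 + 1) / (g4 + 3 * (m - 1)^2 / ((m - 2) * (m - 3)))
  } else {
    (b1^2 + 1) / (b2 + 3)
  }
}

#' Detect conditionally rare taxa (CRTs)
#'
#' Flags taxa that are rare across most time points but occasionally bloom:
#' bimodality coefficient above `b_min` AND peak relative abundance at or
#' above `peak_min`. Bloom time points are the days where a flagged taxon's
#' abundance meets `peak_min`.
#'
#' @param table An `otu_table` with fractional units (observed samples; run
#'   detection before gap interpolation so synthetic peaks cannot arise).
#' @param b_min Bimodality threshold (default 0.8).
#' @param peak_min Peak abundance threshold as a fraction (default 0.10).
#' @return An object of class `crt_report`: a tibble with columns
#'   `taxon_id`, `b`, `peak_abundance`, `is_crt`, `bloom_days` (list
#'   column); attributes `b_min`, `peak_min`.
#' @export
detect_crt <- function(table, b_min = 0.8, peak_min = 0.10) {
  stopifnot(inherits(table, "otu_table"))
  if (table$units != "fractions") stop("detect_crt() needs fractional units")
  out <- purrr::map_dfr(seq_len(n_taxa(table)), function(i) {
    x <- table$values[i, ]
    b <- if (stats::var(x) == 0) NA_real_ else bimodality(x)
    peak <- max(x)
    is_crt <- !is.na(b) && b > b_min && peak >= peak_min
    tibble::tibble(
      taxon_id = table$taxon_ids[i], b = b, peak_abundance = peak,
      is_crt = is_crt,
      bloom_days = list(if (is_crt) table$sample_days[x >= peak_min] else numeric(0))
    )
  })
  attr(out, "b_min") <- b_min
  attr(out, "peak_min") <- peak_min
  class(out) <- c("crt_report", class(out))
  out
}

#' Remove bloom time points flagged by a CRT report
#'
#' Drops every sample column in which any flagged CRT is at or above
#' `threshold` relative abundance. Used for the correlation-robustness
#' check: OTU-OTU correlation structure should be essentially unchanged
#' with and without bloom time points when blooms are rare.
#'
#' @param table The `otu_table` the report was computed on.
#' @param report A [detect_crt()] result.
#' @param threshold Masking abundance threshold (default 0.10).
#' @return An `otu_table` without the masked samples.
#' @export
mask_crt_timepoints <- function(table, report, threshold = 0.10) {
  stopifnot(inherits(table, "otu_table"), inherits(report, "crt_report"))
  crt_ids <- report$taxon_id[report$is_crt]
  if (length(crt_ids) == 0) return(table)
  rows <- match(crt_ids, table$taxon_ids)
  if (anyNA(rows)) stop("report does not match this table's taxa")
  frac <- relative_abundance(table)
  bad <- apply(frac$values[rows, , drop = FALSE] >= threshold, 2, any)
  if (sum(!bad) < 10) stop("masking would leave fewer than 10 samples")
  subset_samples_idx(table, which(!bad))
}
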