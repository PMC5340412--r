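#' Assemble a pipeline configuration
#'
#' Flat key-value configuration consumed by [run_full_pipeline()]. All
#' analysis stages read their parameters from here; `seed` is mandatory so
#' every run is reproducible.
#'
#' @param input An `otu_table`, or a path readable by [read_otu_table()].
#' @param seed Integer seed (mandatory).
#' @param metadata Optional sample-metadata CSV path (for TSV/BIOM inputs
#'   without a `#day` row).
#' @param depth Rarefaction depth (default 10000; `NULL` skips rarefaction).
#' @param days Optional `c(from, to)` day window applied before
#'   interpolation.
#' @param top_n Number of most-abundant taxa analyzed (default 50).
#' @param lags sVAR lag order (default 3).
#' @param l1_ratio,threshold Elastic-net mixing and coefficient floor.
#' @param alpha Significance level for stationarity and Granger calls.
#' @param crt_b_min,crt_peak_min CRT thresholds.
#' @param dmm_k_max,dmm_max_stride State-model scan sizes; `dmm_k_max = 0`
#'   skips the state analysis.
#' @param bin_width Phylogenetic bin width.
#' @param distances Optional distance source: a matrix, a PHYLIP square
#'   matrix path, or an aligned FASTA path; `NULL` skips coherence.
#' @param output_dir Directory for the report bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, seed, metadata = NULL, depth = 10000,
                            days = NULL, top_n = 50, lags = 3,
                            l1_ratio = 0.5, threshold = 1e-3, alpha = 0.05,
                            crt_b_min = 0.8, crt_peak_min = 0.10,
                            dmm_k_max = 8, dmm_max_stride = 5,
                            bin_width = 0.05, distances = NULL,
                            output_dir = tempfile("gutregimes_run_")) {
  if (missing(seed)) stop("`seed` is mandatory")
  cfg <- list(input = input, metadata = metadata, seed = as.integer(seed),
              depth = depth, days = days, top_n = top_n, lags = lags,
              l1_ratio = l1_ratio, threshold = threshold, alpha = alpha,
              crt_b_min = crt_b_min, crt_peak_min = crt_peak_min,
              dmm_k_max = dmm_k_max, dmm_max_stride = dmm_max_stride,
              bin_width = bin_width, distances = distances,
              output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full two-regime analysis
#'
#' Fixed stage order: read/validate, day-window slice, rarefaction,
#' relative abundance, top-n filter, PCHIP gap filling, first-differencing,
#' stationarity screen, sVAR fit, Granger network, correlation matrices
#' (abundances, rates, residuals), phylogenetic coherence (when distances
#' are supplied), CRT detection (on observed, pre-interpolation samples),
#' and the DMM state-decay scan. Every result is written as CSV under
#' `output_dir` together with a JSON manifest of parameters and outputs;
#' rerunning with the same config reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with all stage results plus `manifest`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  # permutation tests and subsampling draw from the RNG: run the whole
  # pipeline under the configured seed so reruns are byte-identical
  with_seed(config$seed, run_pipeline_stages(config))
}

run_pipeline_stages <- function(config) {
  out <- list()
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$output_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    invisible(p)
  }
  tab <- config$input
  if (is.character(tab)) {
    tab <- read_otu_table(tab, metadata = config$metadata)
  }
  stopifnot(inherits(tab, "otu_table"))
  if (!is.null(config$days)) {
    tab <- slice_days(tab, config$days[[1]], config$days[[2]])
  }
  counts <- tab
  if (!is.null(config$depth) && tab$units == "counts") {
    counts <- rarefy(tab, config$depth, seed = config$seed)
  }
  frac <- relative_abundance(counts)
  top <- top_taxa(frac, min(config$top_n, n_taxa(frac)))
  out$alpha_diversity <- alpha_diversity(counts)
  emit(out$alpha_diversity, "alpha_diversity")

  out$crt <- detect_crt(top, b_min = config$crt_b_min,
                        peak_min = config$crt_peak_min)
  emit(dplyr::mutate(out$crt,
                     bloom_days = purrr::map_chr(.data$bloom_days,
                                                 paste, collapse = ";")),
       "crt_report")

  filled <- fill_missing_days(top)
  rates <- first_difference(filled)
  out$stationarity <- stationarity_table(list(analysis = filled),
                                         alpha = config$alpha)
  emit(out$stationarity, "stationarity")

  out$svar <- fit_svar(rates, p = config$lags, l1_ratio = config$l1_ratio,
                       threshold = config$threshold, seed = config$seed,
                       check_stationarity = FALSE)
  emit(tidy(out$svar), "svar_coefficients")
  emit(variance_explained(out$svar), "variance_explained")
  out$granger <- granger_tests(out$svar, rates, alpha = config$alpha)
  emit(dplyr::mutate(out$granger,
                     lags = purrr::map_chr(.data$lags, paste, collapse = ";"),
                     coefficients = purrr::map_chr(.data$coefficients,
                                                   function(v) paste(signif(v, 6), collapse = ";"))),
       "granger_edges")

  if (!is.null(config$distances)) {
    d <- config$distances
    if (is.character(d)) {
      d <- if (grepl("\\.(fa|fasta|fna|aln)$", d, ignore.case = TRUE)) {
        pairwise_distance(d)
      } else {
        read_phylip_distances(d)
      }
    }
    out$coherence <- list(
      abundance = bin_by_distance(correlation_matrix(top), d,
                                  bin_width = config$bin_width),
      rates = bin_by_distance(correlation_matrix(rates), d,
                              bin_width = config$bin_width),
      residuals = bin_by_distance(correlation_matrix(out$svar$residuals), d,
                                  bin_width = config$bin_width),
      coefficients = coefficient_coherence(out$svar, d,
                                           bin_width = config$bin_width)
    )
    coh <- purrr::map_dfr(names(out$coherence), function(nm) {
      dplyr::mutate(glance(out$coherence[[nm]]), matrix = nm,
                    .before = 1)
    })
    emit(coh, "coherence_trends")
  }

  if (config$dmm_k_max > 0) {
    out$state_decay <- state_decay(list(run = counts),
                                   max_stride = config$dmm_max_stride,
                                   k_max = config$dmm_k_max,
                                   seed = config$seed)
    emit(out$state_decay$curve, "state_decay")
    emit(out$state_decay$assignments, "state_assignments")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gutregimes")),
    parameters = config[setdiff(names(config), c("input", "distances"))],
    n_taxa = n_taxa(top), n_samples = n_samples(filled),
    outputs = as.list(paths)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", force = TRUE)
  out$manifest <- manifest
  invisible(out)
}
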