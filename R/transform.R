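#' Rarefy a count table to fixed depth
#'
#' Random sub-sampling without replacement (hypergeometric) so that every
#' retained sample contains exactly `depth` reads. Samples with fewer than
#' `depth` reads are dropped with a warning, matching standard practice.
#'
#' @param table An `otu_table` with count units and integer values.
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A rarefied `otu_table` (counts).
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "otu_table"))
  if (table$units != "counts") stop("rarefy() needs a count table")
  if (length(depth) != 1 || depth <= 0 || depth != round(depth)) {
    stop("`depth` must be a positive integer")
  }
  if (any(table$values != round(table$values))) stop("counts must be integers")
  cs <- colSums(table$values)
  keep <- cs >= depth
  if (!any(keep)) stop("every sample is below the rarefaction depth")
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(table$sample_ids[!keep], collapse = ", ")))
  }
  tab <- subset_samples_idx(table, which(keep))
  out <- with_seed(seed, {
    apply(tab$values, 2, function(col) {
      pool <- rep.int(seq_along(col), col)
      draw <- if (length(pool) == depth) pool else sample(pool, depth)
      tabulate(draw, nbins = length(col))
    })
  })
  otu_table(out, tab$taxon_ids, tab$sample_days, tab$sample_ids,
            units = "counts", taxonomy = tab$taxonomy)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total. Idempotent on fractional input.
#'
#' @param table An `otu_table`.
#' @return An `otu_table` with `units = "fractions"`.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (table$units == "fractions") return(table)
  cs <- colSums(table$values)
  if (any(cs == 0)) {
    stop("all-zero sample column: ", table$sample_ids[cs == 0][[1]])
  }
  otu_table(sweep(table$values, 2, cs, "/"), table$taxon_ids,
            table$sample_days, table$sample_ids, units = "fractions",
            taxonomy = table$taxonomy)
}

#' Keep the n most abundant taxa
#'
#' Ranks taxa by mean relative abundance across samples (counts are
#' converted to fractions internally for ranking only). Ties are broken by
#' lexicographic taxon id so the selection is deterministic.
#'
#' @param table An `otu_table`.
#' @param n Number of taxa to retain.
#' @return An `otu_table` with `n` taxa, in decreasing rank order.
#' @export
top_taxa <- function(table, n) {
  stopifnot(inherits(table, "otu_table"))
  if (length(n) != 1 || n <= 0 || n != round(n)) stop("`n` must be a positive integer")
  if (n > n_taxa(table)) stop("`n` exceeds the number of taxa")
  frac <- relative_abundance(table)
  score <- rowMeans(frac$values)
  ord <- order(-score, table$taxon_ids)
  subset_taxa_idx(table, ord[seq_len(n)])
}

#' Per-sample Shannon diversity and effective species number
#'
#' Shannon entropy H (natural log, over nonzero fractions) and the effective
#' number of species `n_eff = exp(H)`.
#'
#' @param table An `otu_table`.
#' @return A tibble with columns `sample_id`, `day`, `shannon`, `n_eff`.
#' @export
alpha_diversity <- function(table) {
  frac <- relative_abundance(table)
  h <- apply(frac$values, 2, function(f) {
    f <- f[f > 0]
    -sum(f * log(f))
  })
  tibble::tibble(sample_id = frac$sample_ids, day = frac$sample_days,
                 shannon = unname(h), n_eff = unname(exp(h)))
}

#' Pairwise Jensen-Shannon divergence between samples
#'
#' Base-e JSD between every pair of sample columns of a fractional table;
#' entries lie in `[0, log 2]`.
#'
#' @param table An `otu_table` with fractional units.
#' @return A symmetric `m x m` matrix with sample ids as dimnames.
#' @export
jensen_shannon <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (table$units != "fractions") stop("jensen_shannon() needs fractional units")
  m <- n_samples(table)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hcol <- apply(table$values, 2, H)
  out <- matrix(0, m, m, dimnames = list(table$sample_ids, table$sample_ids))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      mix <- (table$values[, i] + table$values[, j]) / 2
      d <- H(mix) - (hcol[i] + hcol[j]) / 2
      out[i, j] <- out[j, i] <- max(d, 0)
    }
  }
  out
}

#' Taxon sharing across datasets
#'
#' A taxon counts as present in a dataset when it is detected (abundance
#' greater than zero) in at least `min_occurrence` samples. Reports pairwise
#' shared-taxon counts (per-dataset totals on the diagonal), the full
#' intersection across all datasets, the fraction of each dataset's reads
#' carried by full-intersection taxa, and each shared taxon's median
#' relative abundance per dataset.
#'
#' @param tables A named list of `otu_table`s (>= 2).
#' @param min_occurrence Minimum number of samples for presence (default 1).
#' @return An object of class `shared_taxa_report`: list with
#'   `pairwise_counts`, `full_intersection` (character vector),
#'   `abundance_fraction` (named numeric), and `median_abundance` (tibble
#'   with columns `dataset`, `taxon_id`, `median_abundance`).
#' @export
shared_taxa <- function(tables, min_occurrence = 1) {
  if (length(tables) < 2) stop("need at least two tables")
  stopifnot(all(vapply(tables, inherits, logical(1), "otu_table")))
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  present <- lapply(tables, function(t) {
    t$taxon_ids[rowSums(t$values > 0) >= min_occurrence]
  })
  k <- length(tables)
  pc <- matrix(0L, k, k, dimnames = list(names(tables), names(tables)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pc[i, j] <- length(intersect(present[[i]], present[[j]]))
    }
  }
  full <- Reduce(intersect, present)
  abund_frac <- vapply(tables, function(t) {
    tot <- sum(t$values)
    if (tot == 0) return(NA_real_)
    sum(t$values[t$taxon_ids %in% full, , drop = FALSE]) / tot
  }, numeric(1))
  med <- purrr::map_dfr(names(tables), function(nm) {
    fr <- relative_abundance(tables[[nm]])
    idx <- match(full, fr$taxon_ids)
    tibble::tibble(
      dataset = nm, taxon_id = full,
      median_abundance = apply(fr$values[idx, , drop = FALSE], 1, stats::median)
    )
  })
  structure(
    list(pairwise_counts = pc, full_intersection = sort(full),
         abundance_fraction = abund_frac, median_abundance = med,
         min_occurrence = min_occurrence),
    class = "shared_taxa_report"
  )
}

#' @export
print.shared_taxa_report <- function(x, ...) {
  cat(sprintf("<shared_taxa_report> %d datasets, %d taxa in full intersection\n",
              nrow(x$pairwise_counts), length(x$full_intersection)))
  print(x$pairwise_counts)
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (length(seed) != 1 || is.na(seed)) stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
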