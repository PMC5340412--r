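#' Pairwise phylogenetic distances from an alignment
#'
#' Model-corrected distances between aligned representative sequences, via
#' the standard substitution-model estimators (F84 by default, matching the
#' classic dnadist default; Jukes-Cantor available). Sites with non-ACGT
#' symbols in either sequence of a pair are excluded pairwise. Saturated
#' pairs whose correction is undefined are set to the largest finite
#' distance in the matrix, with a warning.
#'
#' @param alignment Path to an aligned FASTA file, or an `ape::DNAbin`
#'   alignment.
#' @param model `"F84"` or `"JC"`.
#' @return A symmetric distance matrix with taxon ids as dimnames.
#' @export
pairwise_distance <- function(alignment, model = c("F84", "JC")) {
  model <- match.arg(model)
  if (is.character(alignment)) {
    alignment <- ape::read.dna(alignment, format = "fasta")
  }
  if (!inherits(alignment, "DNAbin")) stop("alignment must be FASTA path or DNAbin")
  mod <- if (model == "JC") "JC69" else "F84"
  d <- ape::dist.dna(alignment, model = mod, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  bad <- !is.finite(d)
  diag(bad) <- FALSE
  if (any(bad)) {
    mx <- max(d[is.finite(d)])
    d[bad] <- mx
    warning(sum(bad) / 2, " saturated pair(s) set to the maximum finite distance")
  }
  d
}

#' Spearman correlation matrix between taxa
#'
#' Column-wise Spearman's rho of a samples-by-taxa value matrix (an
#' abundance table transposed, a rate matrix, or an sVAR residual matrix).
#' Ties are mid-ranked. Constant columns get `NA` correlations and are
#' excluded downstream.
#'
#' @param values A samples x taxa numeric matrix (or `rate_matrix` /
#'   `otu_table`, converted automatically).
#' @return A symmetric taxon x taxon matrix with unit diagonal.
#' @export
correlation_matrix <- function(values) {
  if (inherits(values, "otu_table")) values <- t(values$values)
  if (inherits(values, "rate_matrix")) values <- values$values
  values <- as.matrix(values)
  if (nrow(values) < 10) stop("need at least 10 rows (samples)")
  const <- apply(values, 2, function(x) stats::var(x) == 0)
  rho <- suppressWarnings(stats::cor(values, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)
  rho
}

#' Bin pairwise coefficients by phylogenetic distance
#'
#' Assigns every (unordered) taxon pair to half-open distance bins
#' `[k*w, (k+1)*w)`, reports the mean coefficient and pair count per bin,
#' and tests the global distance-coefficient trend two ways: a naive
#' pair-level Spearman test (pairs treated as independent) and a Mantel
#' permutation test (999 permutations), which respects the fact that pairs
#' sharing a taxon are dependent. Pairs with undefined coefficients are
#' dropped.
#'
#' @param coefficients Symmetric taxon x taxon matrix (correlations or
#'   symmetrized model coefficients).
#' @param dist Symmetric distance matrix over the same taxa.
#' @param bin_width Bin width in substitution units (default 0.05).
#' @param permutations Mantel permutations (default 999; 0 skips Mantel).
#' @return An object of class `coherence_result`: `bins` (tibble with
#'   `bin_low`, `bin_high`, `mean_coefficient`, `n_pairs`), `trend_rho`,
#'   `trend_p_pairs`, `mantel_p`, `n_pairs`.
#' @export
bin_by_distance <- function(coefficients, dist, bin_width = 0.05,
                            permutations = 999) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  coefficients <- as.matrix(coefficients)
  dist <- as.matrix(dist)
  if (!is.null(rownames(coefficients)) && !is.null(rownames(dist))) {
    common <- intersect(rownames(coefficients), rownames(dist))
    if (length(common) < 3) stop("taxon sets do not match")
    coefficients <- coefficients[common, common]
    dist <- dist[common, common]
  }
  if (any(dim(coefficients) != dim(dist))) stop("matrix dimensions differ")
  ut <- upper.tri(dist)
  d <- dist[ut]
  v <- coefficients[ut]
  keep <- is.finite(v) & is.finite(d)
  all_defined <- all(keep)
  d0 <- d[keep]; v0 <- v[keep]
  idx <- floor(d0 / bin_width)
  bins <- tibble::tibble(bin = idx) |>
    dplyr::mutate(coefficient = v0) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_coefficient = mean(.data$coefficient),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(bin_low = .data$bin * bin_width,
                     bin_high = (.data$bin + 1) * bin_width,
                     mean_coefficient = .data$mean_coefficient,
                     n_pairs = .data$n_pairs) |>
    dplyr::arrange(.data$bin_low)
  trend_rho <- NA_real_; trend_p <- NA_real_; mantel_p <- NA_real_
  if (length(unique(v0)) > 1 && length(unique(d0)) > 1) {
    ct <- suppressWarnings(stats::cor.test(d0, v0, method = "spearman"))
    trend_rho <- unname(ct$estimate)
    trend_p <- ct$p.value
    if (permutations > 0 && all_defined) {
      mt <- vegan::mantel(stats::as.dist(dist), stats::as.dist(coefficients),
                          method = "spearman", permutations = permutations)
      # one-sided p in the observed direction, from the permutation draws
      perm <- mt$perm
      mantel_p <- if (mt$statistic >= 0) {
        (sum(perm >= mt$statistic) + 1) / (length(perm) + 1)
      } else {
        (sum(perm <= mt$statistic) + 1) / (length(perm) + 1)
      }
    }
  }
  structure(list(bins = bins, trend_rho = trend_rho,
                 trend_p_pairs = trend_p, mantel_p = mantel_p,
                 n_pairs = length(v0), bin_width = bin_width),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d pairs, trend rho = %.3f (pairwise p = %.2g, Mantel p = %s)\n",
              x$n_pairs, x$trend_rho, x$trend_p_pairs,
              ifelse(is.na(x$mantel_p), "NA", format(x$mantel_p, digits = 3))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coherence_result <- function(x, ...) x$bins

#' @exportS3Method generics::glance
glance.coherence_result <- function(x, ...) {
  tibble::tibble(trend_rho = x$trend_rho, trend_p_pairs = x$trend_p_pairs,
                 mantel_p = x$mantel_p, n_pairs = x$n_pairs,
                 bin_width = x$bin_width)
}

#' Phylogenetic coherence of sVAR coefficients
#'
#' Applies the distance-binned trend analysis to the fitted model's
#' cross-coefficients, symmetrized as
#' `(sum_k R_k[i, j] + sum_k R_k[j, i]) / 2`. A model with no
#' off-diagonal support returns all-zero bins with an undefined trend.
#'
#' @param model An `svar_fit`.
#' @param dist Distance matrix over the model's taxa.
#' @param bin_width Bin width (default 0.05).
#' @param permutations Mantel permutations (default 999).
#' @return A [bin_by_distance()] result.
#' @export
coefficient_coherence <- function(model, dist, bin_width = 0.05,
                                  permutations = 999) {
  stopifnot(inherits(model, "svar_fit"))
  S <- Reduce(`+`, model$coefficients)
  sym <- (S + t(S)) / 2
  diag(sym) <- 0
  dimnames(sym) <- list(model$taxon_ids, model$taxon_ids)
  bin_by_distance(sym, dist, bin_width = bin_width,
                  permutations = permutations)
}

#' Simulate a clade-structured ultrametric phylogeny
#'
#' Taxa are split evenly into `n_clades` groups; within-clade distances
#' come from a random coalescent tree rescaled to maximum height
#' `within_height`, and all between-clade distances equal
#' `2 * between_height`. Within-clade distances are therefore always
#' smaller than between-clade ones.
#'
#' @param n_taxa Number of taxa.
#' @param n_clades Number of clades (<= `n_taxa`).
#' @param seed Integer seed.
#' @param within_height Half the maximum within-clade distance (default 0.05).
#' @param between_height Half the between-clade distance (default 0.5).
#' @return A list with `dist` (matrix) and `clades` (integer labels).
#' @export
simulate_phylogeny <- function(n_taxa, n_clades, seed = 1,
                               within_height = 0.05, between_height = 0.5) {
  if (n_clades > n_taxa || n_clades < 1) stop("need 1 <= n_clades <= n_taxa")
  labels <- sort(rep_len(seq_len(n_clades), n_taxa))
  ids <- sprintf("otu%03d", seq_len(n_taxa))
  D <- matrix(2 * between_height, n_taxa, n_taxa, dimnames = list(ids, ids))
  with_seed(seed, {
    for (cl in seq_len(n_clades)) {
      members <- which(labels == cl)
      nc <- length(members)
      if (nc == 1) next
      if (nc == 2) {
        sub <- matrix(c(0, 2 * within_height, 2 * within_height, 0), 2, 2)
      } else {
        tr <- ape::rcoal(nc)
        sub <- ape::cophenetic.phylo(tr)
        sub <- sub / max(sub) * 2 * within_height
        sub <- sub[order(as.integer(sub("t", "", rownames(sub)))), ]
        sub <- sub[, order(as.integer(sub("t", "", colnames(sub))))]
      }
      D[members, members] <- sub
    }
  })
  diag(D) <- 0
  list(dist = D, clades = labels)
}
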