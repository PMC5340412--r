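# Synthetic data generators. Each returns the generating truth alongside
# the data so recovery can be tested end to end without any downloads.

# draw sparse VAR(p) coefficient matrices with given self/cross structure,
# redrawing until the companion spectral radius is < 0.95
draw_var_coefficients <- function(n_taxa, p, n_cross, cross_coef, self_coef,
                                  max_tries = 100) {
  off <- which(row(diag(n_taxa)) != col(diag(n_taxa)))
  for (try in seq_len(max_tries)) {
    coefs <- lapply(seq_len(p), function(k) matrix(0, n_taxa, n_taxa))
    if (self_coef != 0) diag(coefs[[1]]) <- self_coef
    if (n_cross > 0) {
      slots <- sample(rep(seq_len(p), length.out = n_cross))
      pos <- sample(off, n_cross)
      sgn <- sample(c(-1, 1), n_cross, replace = TRUE)
      for (e in seq_len(n_cross)) {
        coefs[[slots[e]]][pos[e]] <- sgn[e] * cross_coef
      }
    }
    if (companion_spectral_radius(coefs) < 0.95) return(coefs)
  }
  stop("could not draw a stationary coefficient set in ", max_tries, " tries")
}

# clade-block innovation covariance: unit-free scale sd, within-clade
# correlation rho, zero between clades
clade_block_cov <- function(clades, sd, rho) {
  n <- length(clades)
  S <- outer(clades, clades, `==`) * rho
  diag(S) <- 1
  S * sd^2
}

rmvnorm_chol <- function(n, chol_S) {
  matrix(stats::rnorm(n * ncol(chol_S)), n) %*% chol_S
}

#' Simulate a rate matrix from a known sparse VAR(p)
#'
#' Direct simulation of the first-differenced (rate) process: `n_cross`
#' off-diagonal lag coefficients of magnitude `cross_coef` (random sign,
#' random lag), optional self terms, Gaussian innovations (optionally
#' clade-block correlated). Used to test coefficient and support recovery
#' against exact truth.
#'
#' @param n_taxa,n_days Dimensions of the output.
#' @param p Lag order of the generating VAR (default 1).
#' @param n_cross Number of nonzero cross coefficients (default 20).
#' @param cross_coef Magnitude of cross coefficients (default 0.3).
#' @param self_coef Diagonal lag-1 coefficient (default 0).
#' @param innovation_sd Innovation standard deviation (default 0.1).
#' @param clades Optional clade labels; with `clade_cov` they give the
#'   innovations a within-clade correlation.
#' @param clade_cov Within-clade innovation correlation (default 0).
#' @param seed Integer seed.
#' @return A list with `rates` (a [rate_matrix()]) and `truth`
#'   (`coefficients`, `innovation_cov`, `clades`, `seed`).
#' @export
simulate_var_rates <- function(n_taxa, n_days, p = 1, n_cross = 20,
                               cross_coef = 0.3, self_coef = 0,
                               innovation_sd = 0.1, clades = NULL,
                               clade_cov = 0, seed = 1) {
  with_seed(seed, {
    coefs <- draw_var_coefficients(n_taxa, p, n_cross, cross_coef, self_coef)
    if (is.null(clades)) clades <- seq_len(n_taxa)
    S <- clade_block_cov(clades, innovation_sd, clade_cov)
    ch <- chol(S)
    burn <- 100
    Tt <- n_days + burn
    E <- rmvnorm_chol(Tt, ch)
    Z <- matrix(0, Tt, n_taxa)
    for (t in (p + 1):Tt) {
      z <- E[t, ]
      for (k in seq_len(p)) z <- z + coefs[[k]] %*% Z[t - k, ]
      Z[t, ] <- z
    }
    Z <- Z[(burn + 1):Tt, , drop = FALSE]
    ids <- sprintf("otu%03d", seq_len(n_taxa))
    colnames(Z) <- ids
    list(rates = rate_matrix(Z, ids, day_from = seq_len(n_days),
                             day_to = seq_len(n_days) + 1,
                             source_units = "fractions"),
         truth = list(coefficients = coefs, innovation_cov = S,
                      clades = clades, seed = seed))
  })
}

#' Simulate an OTU count time series with two dynamic regimes
#'
#' Generates latent log-abundance dynamics with an autoregressive regime
#' (sparse VAR(p) on the daily deltas, phylogeny-independent coupling) and
#' a non-autoregressive regime (innovations with clade-block covariance:
#' related taxa co-fluctuate, unrelated taxa do not). Latent levels damp
#' back toward fixed per-taxon carrying capacities, are mapped to
#' compositions by softmax normalization, and sampled as multinomial counts
#' at fixed depth. The generating parameters are returned as truth.
#'
#' @param n_taxa Number of taxa (default 50).
#' @param n_days Number of days (default 300).
#' @param p Lag order of the latent VAR (default 1).
#' @param sparsity Fraction of ordered off-diagonal pairs with a nonzero
#'   cross coefficient (default 0.04).
#' @param ar_strength Magnitude of self and cross lag coefficients
#'   (default 0.4; 0 disables the autoregressive regime).
#' @param clade_cov_strength Within-clade innovation correlation
#'   (default 0.5; 0 disables the clade regime).
#' @param n_clades Number of clades in the simulated phylogeny (default 5).
#' @param depth Reads per sample (default 10000).
#' @param innovation_sd Latent innovation standard deviation (default 0.12:
#'   a ~12 percent typical day-to-day abundance change).
#' @param level_damping Day-to-day retention of level deviations
#'   (default 0.9; mean reversion toward carrying capacity with a half-life
#'   of about a week).
#' @param abundance_range Carrying-capacity ladder: target fractions of the
#'   most and least abundant taxon (default `c(0.2, 0.001)`, the steep
#'   profile typical of gut top-50 tables; flatter profiles weaken the
#'   compositional closure).
#' @param seed Integer seed.
#' @return A list with `counts` (an `otu_table`), `truth` (list:
#'   `coefficients`, `innovation_cov`, `phylogeny`, `clades`,
#'   `carrying_capacity`, `level_damping`, `seed`).
#' @export
simulate_svar_counts <- function(n_taxa = 50, n_days = 300, p = 1,
                                 sparsity = 0.04, ar_strength = 0.4,
                                 clade_cov_strength = 0.5, n_clades = 5,
                                 depth = 10000, innovation_sd = 0.12,
                                 level_damping = 0.9,
                                 abundance_range = c(0.2, 0.001), seed = 1) {
  stopifnot(n_taxa >= 2, n_days >= p + 20, depth >= 100,
            sparsity >= 0, sparsity < 1,
            clade_cov_strength >= 0, clade_cov_strength < 1,
            level_damping >= 0, level_damping < 1)
  phy <- simulate_phylogeny(n_taxa, n_clades, seed = seed + 1L)
  with_seed(seed, {
    n_cross <- round(sparsity * n_taxa * (n_taxa - 1))
    coefs <- draw_var_coefficients(n_taxa, p, n_cross,
                                   cross_coef = ar_strength,
                                   self_coef = ar_strength)
    S <- clade_block_cov(phy$clades, innovation_sd, clade_cov_strength)
    ch <- chol(S)
    # carrying capacities: geometric abundance ladder over abundance_range,
    # assigned to taxa in random order so abundance is not confounded with
    # clade membership (clade labels follow taxon order)
    cc <- log(abundance_range[[1]]) + (seq_len(n_taxa) - 1) / (n_taxa - 1) *
      (log(abundance_range[[2]]) - log(abundance_range[[1]]))
    cc <- sample(cc)
    burn <- 100
    Tt <- n_days + burn
    E <- rmvnorm_chol(Tt, ch)
    Z <- matrix(0, Tt, n_taxa)   # latent deltas, VAR(p)
    Y <- matrix(0, Tt, n_taxa)   # latent level deviations from cc
    for (t in (p + 1):Tt) {
      z <- E[t, ]
      for (k in seq_len(p)) z <- z + coefs[[k]] %*% Z[t - k, ]
      Z[t, ] <- z
      Y[t, ] <- level_damping * Y[t - 1, ] + Z[t, ]
    }
    Y <- Y[(burn + 1):Tt, , drop = FALSE]
    logab <- sweep(Y, 2, cc, "+")
    frac <- exp(logab)
    frac <- frac / rowSums(frac)
    counts <- t(apply(frac, 1, function(pr) {
      as.integer(stats::rmultinom(1, depth, pr))
    }))
    ids <- rownames(phy$dist)
    tab <- otu_table(t(counts), ids, sample_days = seq_len(n_days),
                     units = "counts")
    list(counts = tab,
         truth = list(coefficients = coefs, innovation_cov = S,
                      phylogeny = phy$dist, clades = phy$clades,
                      carrying_capacity = cc, level_damping = level_damping,
                      seed = seed))
  })
}

#' Inject conditionally-rare-taxon blooms into a table
#'
#' Replaces selected taxa's trajectories with a flat baseline punctuated by
#' scheduled blooms: the abundance jumps to `peak` and decays geometrically
#' by `decay` per day over `duration_days`. Columns are renormalized if the
#' table is fractional. The bloom schedule is returned as truth.
#'
#' @param table An `otu_table` (fractions recommended).
#' @param n_crt Number of taxa to convert (default 3).
#' @param baseline Baseline fraction (default 0.001).
#' @param peak Peak fraction (default 0.3; must exceed `baseline`).
#' @param duration_days Bloom length in days (default 5).
#' @param decay Per-day geometric decay factor in (0, 1) (default 0.5).
#' @param n_blooms Blooms per converted taxon (default 1).
#' @param seed Integer seed.
#' @return A list with `table` (modified `otu_table`) and `schedule`
#'   (tibble: `taxon_id`, `start_day`, `duration_days`, `peak`).
#' @export
inject_crt_blooms <- function(table, n_crt = 3, baseline = 0.001,
                              peak = 0.3, duration_days = 5, decay = 0.5,
                              n_blooms = 1, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (n_crt > n_taxa(table)) stop("n_crt exceeds the number of taxa")
  if (peak <= baseline) stop("`peak` must exceed `baseline`")
  if (n_crt == 0) {
    return(list(table = table, schedule = tibble::tibble(
      taxon_id = character(), start_day = numeric(),
      duration_days = numeric(), peak = numeric())))
  }
  m <- n_samples(table)
  if (m < duration_days * n_blooms * 2) stop("series too short for the bloom schedule")
  with_seed(seed, {
    crt_rows <- sample(n_taxa(table), n_crt)
    vals <- table$values
    sched <- list()
    for (r in crt_rows) {
      prof <- rep(baseline, m)
      starts <- integer(0)
      for (b in seq_len(n_blooms)) {
        ok <- FALSE
        for (try in seq_len(200)) {
          s <- sample(m - duration_days + 1, 1)
          if (all(abs(s - starts) >= duration_days)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place non-overlapping blooms for taxon ",
                      table$taxon_ids[r])
        starts <- c(starts, s)
        idx <- s:(s + duration_days - 1)
        prof[idx] <- pmax(prof[idx], peak * decay^(seq_along(idx) - 1))
        sched[[length(sched) + 1]] <- tibble::tibble(
          taxon_id = table$taxon_ids[r],
          start_day = table$sample_days[s],
          duration_days = duration_days, peak = peak)
      }
      vals[r, ] <- prof
    }
    if (table$units == "fractions") {
      vals <- sweep(vals, 2, colSums(vals), "/")
    }
    list(table = otu_table(vals, table$taxon_ids, table$sample_days,
                           table$sample_ids, units = table$units,
                           taxonomy = table$taxonomy),
         schedule = dplyr::bind_rows(sched))
  })
}

#' Simulate counts from a Dirichlet-multinomial mixture
#'
#' Each sample's composition is drawn from its state's Dirichlet
#' distribution, then counts are multinomial at fixed depth. In
#' `"auto"` mode the K alpha vectors are built with disjoint dominant
#' taxon blocks, giving well-separated states.
#'
#' @param n_taxa Number of taxa.
#' @param samples_per_state Integer vector; its length is the number of
#'   states K, entries are samples per state.
#' @param alphas `"auto"` or an `n_taxa x K` matrix of positive Dirichlet
#'   parameters.
#' @param depth Reads per sample (default 1000).
#' @param seed Integer seed.
#' @param dominant_alpha,background_alpha Parameters of the auto-separated
#'   construction (defaults 5 and 0.05).
#' @return A list with `counts` (an `otu_table`, samples in state order)
#'   and `state_labels` (integer vector).
#' @export
simulate_dmm <- function(n_taxa, samples_per_state, alphas = "auto",
                         depth = 1000, seed = 1, dominant_alpha = 5,
                         background_alpha = 0.05) {
  K <- length(samples_per_state)
  stopifnot(K >= 1, all(samples_per_state >= 1))
  if (identical(alphas, "auto")) {
    blk <- floor(n_taxa / K)
    if (blk < 1) stop("need at least one dominant taxon per state")
    alphas <- matrix(background_alpha, n_taxa, K)
    for (k in seq_len(K)) {
      alphas[((k - 1) * blk + 1):(k * blk), k] <- dominant_alpha
    }
  }
  alphas <- as.matrix(alphas)
  if (nrow(alphas) != n_taxa || ncol(alphas) != K) stop("alphas must be n_taxa x K")
  if (any(alphas <= 0)) stop("Dirichlet parameters must be positive")
  labels <- rep(seq_len(K), times = samples_per_state)
  m <- length(labels)
  counts <- with_seed(seed, {
    vapply(seq_len(m), function(i) {
      a <- alphas[, labels[i]]
      g <- stats::rgamma(n_taxa, shape = a)
      pr <- g / sum(g)
      as.integer(stats::rmultinom(1, depth, pr))
    }, integer(n_taxa))
  })
  ids <- sprintf("otu%03d", seq_len(n_taxa))
  tab <- otu_table(counts, ids, sample_days = seq_len(m), units = "counts")
  list(counts = tab, state_labels = labels)
}

#' Randomly remove interior days from a table
#'
#' Emulates sampling gaps: a `fraction` of interior days is dropped
#' uniformly at random; the first and last day are always kept so
#' interpolation stays within the observed range.
#'
#' @param table An `otu_table`.
#' @param fraction Missing-day rate in \[0, 0.5).
#' @param seed Integer seed.
#' @return An `otu_table` with gaps.
#' @export
drop_days <- function(table, fraction, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (fraction < 0 || fraction >= 0.5) stop("`fraction` must be in [0, 0.5)")
  m <- n_samples(table)
  n_drop <- round(fraction * m)
  if (n_drop == 0) return(table)
  with_seed(seed, {
    interior <- 2:(m - 1)
    gone <- sample(interior, min(n_drop, length(interior)))
    subset_samples_idx(table, setdiff(seq_len(m), gone))
  })
}
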