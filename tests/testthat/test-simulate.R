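test_that("simulated phylogenies separate clades at every seed", {
  for (seed in 1:5) {
    phy <- simulate_phylogeny(20, 4, seed = seed)
    same <- outer(phy$clades, phy$clades, `==`)
    ut <- upper.tri(phy$dist)
    expect_lt(max(phy$dist[ut][same[ut]]), min(phy$dist[ut][!same[ut]]))
  }
  deg <- simulate_phylogeny(6, 6, seed = 1)
  expect_true(all(deg$dist[upper.tri(deg$dist)] == max(deg$dist)))
  one <- simulate_phylogeny(6, 1, seed = 1)
  expect_true(all(one$dist[upper.tri(one$dist)] <= 0.1 + 1e-9))
  expect_error(simulate_phylogeny(3, 5), "n_clades")
})

test_that("count generator respects depth, determinism, and stationarity", {
  sim <- simulate_svar_counts(n_taxa = 15, n_days = 80, depth = 2000, seed = 2)
  expect_true(all(colSums(sim$counts$values) == 2000))
  sim2 <- simulate_svar_counts(n_taxa = 15, n_days = 80, depth = 2000, seed = 2)
  expect_identical(sim$counts$values, sim2$counts$values)
  expect_lt(companion_spectral_radius(sim$truth$coefficients), 0.95)
})

test_that("without coupling or clade covariance, taxa rates are independent", {
  # compositional closure mechanically anticorrelates the dominant taxa's
  # fraction deltas; the independence null applies away from those pairs
  sim <- simulate_svar_counts(n_taxa = 20, n_days = 300, ar_strength = 0,
                              clade_cov_strength = 0, depth = 50000, seed = 3)
  fr <- relative_abundance(sim$counts)
  keep <- fr$taxon_ids[rank(-rowMeans(fr$values)) > 3]
  rho <- correlation_matrix(first_difference(fr))[keep, keep]
  offd <- abs(rho[upper.tri(rho)])
  expect_gte(mean(offd < 0.2), 0.95)
})

test_that("the full pipeline recovers planted structure from deep counts", {
  # deep-sequencing validation regime: weak compositional closure, low
  # measurement noise; see the methods vignette for why survey-depth
  # counts attenuate support recovery
  f1s <- vapply(1:2, function(seed) {
    sim <- simulate_svar_counts(n_taxa = 30, n_days = 600, sparsity = 0.04,
                                ar_strength = 0.4, clade_cov_strength = 0.5,
                                depth = 1e6, innovation_sd = 0.05,
                                abundance_range = c(0.05, 0.005), seed = seed)
    rates <- first_difference(relative_abundance(sim$counts))
    fit <- fit_svar(rates, p = 1, seed = seed, check_stationarity = FALSE)
    truth <- sim$truth$coefficients[[1]]
    est <- fit$coefficients[[1]]
    tp <- sum(truth != 0 & est != 0)
    fp <- sum(truth == 0 & est != 0)
    fn <- sum(truth != 0 & est == 0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  expect_gte(mean(f1s), 0.8)
})

test_that("injected blooms are found by the detector and shift diversity", {
  sim <- simulate_svar_counts(n_taxa = 50, n_days = 200, ar_strength = 0.2,
                              clade_cov_strength = 0.3, depth = 10000, seed = 5)
  frac <- relative_abundance(sim$counts)
  inj <- inject_crt_blooms(frac, n_crt = 4, baseline = 0.001, peak = 0.3,
                           duration_days = 5, seed = 5)
  rep_ <- detect_crt(inj$table)
  planted <- unique(inj$schedule$taxon_id)
  flagged <- rep_$taxon_id[rep_$is_crt]
  expect_setequal(flagged, planted)   # precision = recall = 1
  # diversity deviations co-occur with bloom days
  ad <- alpha_diversity(inj$table)
  bloom_days <- unlist(lapply(seq_len(nrow(inj$schedule)), function(i) {
    inj$schedule$start_day[i] + 0:(inj$schedule$duration_days[i] - 1)
  }))
  dev <- abs(ad$n_eff - stats::median(ad$n_eff))
  expect_gt(cor(dev, ad$day %in% bloom_days), 0)
  # n_crt = 0 is the identity
  none <- inject_crt_blooms(frac, n_crt = 0, seed = 1)
  expect_identical(none$table, frac)
})

test_that("DMM sampler hits requested depth and drop_days keeps endpoints", {
  sd_ <- simulate_dmm(12, c(5, 5), depth = 500, seed = 6)
  expect_true(all(colSums(sd_$counts$values) == 500))
  expect_equal(sd_$state_labels, rep(1:2, each = 5))
  tab <- ar1_table(n = 3, m = 50, seed = 7)
  gap <- drop_days(tab, 0.2, seed = 7)
  expect_equal(gap$sample_days[[1]], tab$sample_days[[1]])
  expect_equal(max(gap$sample_days), max(tab$sample_days))
  expect_identical(drop_days(tab, 0, seed = 1), tab)
  expect_error(drop_days(tab, 0.7, seed = 1), "fraction")
  # interpolation error at dropped days is below the daily-change scale
  fr <- relative_abundance(tab)
  gap_fr <- drop_days(fr, 0.15, seed = 8)
  filled <- fill_missing_days(gap_fr, renormalize = FALSE)
  dropped <- setdiff(fr$sample_days, gap_fr$sample_days)
  err <- fr$values[, match(dropped, fr$sample_days)] -
    filled$values[, match(dropped, filled$sample_days)]
  daily_sd <- mean(apply(t(diff(t(fr$values))), 1, stats::sd))
  expect_lt(sqrt(mean(err^2)), daily_sd)
})
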