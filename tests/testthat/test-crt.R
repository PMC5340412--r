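test_that("bimodality coefficient reaches its distributional limits", {
  set.seed(2)
  expect_lt(abs(bimodality(runif(1e5)) - 5 / 9), 0.03)
  expect_lt(abs(bimodality(rnorm(1e5)) - 1 / 3), 0.03)
  two_point <- rep(c(0, 0.3), 5e4)
  expect_lt(abs(bimodality(two_point) - 1), 0.01)
  # scale invariance
  x <- rgamma(500, 2)
  expect_equal(bimodality(x), bimodality(x * 13.7), tolerance = 1e-12)
  expect_error(bimodality(rep(1, 10)), "constant")
  expect_error(bimodality(1:3), "at least 4")
})

test_that("CRT detection flags blooms and respects threshold monotonicity", {
  m <- 120
  baseline <- rep(0.001, m)
  bloom <- baseline
  bloom[40:44] <- 0.3 * 0.6^(0:4)
  smooth <- 0.10 + 0.05 * sin(seq_len(m) / 6)
  rest <- 1 - bloom - smooth
  tab <- otu_table(rbind(bloom, smooth, rest),
                   c("bloomer", "oscillator", "bulk"), seq_len(m),
                   units = "fractions")
  rep_ <- detect_crt(tab)
  expect_true(rep_$is_crt[rep_$taxon_id == "bloomer"])
  expect_false(rep_$is_crt[rep_$taxon_id == "oscillator"])
  expect_equal(rep_$bloom_days[rep_$taxon_id == "bloomer"][[1]], c(40, 41, 42))
  # raising either threshold never adds CRTs
  expect_equal(sum(detect_crt(tab, b_min = 10)$is_crt), 0L)
  expect_lte(sum(detect_crt(tab, peak_min = 0.5)$is_crt), sum(rep_$is_crt))
})

test_that("masking removes exactly the bloom time points", {
  m <- 60
  bloom <- rep(0.001, m)
  bloom[20:22] <- c(0.4, 0.25, 0.12)
  shares <- rep(1 / 15, 15)
  bg <- outer(shares, 1 - bloom)       # background spread over 15 taxa
  tab <- otu_table(rbind(bloom, bg), c("crt", sprintf("bg%02d", 1:15)),
                   seq_len(m), units = "fractions")
  rep_ <- detect_crt(tab)
  masked <- mask_crt_timepoints(tab, rep_)
  expect_equal(setdiff(tab$sample_days, masked$sample_days), c(20, 21, 22))
  # no CRTs: identity
  quiet <- otu_table(rbind(rep(0.5, m), rep(0.5, m)), c("a", "b"),
                     seq_len(m), units = "fractions")
  expect_identical(mask_crt_timepoints(quiet, detect_crt(quiet)), quiet)
})

test_that("rare blooms barely perturb the rate correlation structure", {
  sim <- simulate_svar_counts(n_taxa = 20, n_days = 150, ar_strength = 0.3,
                              clade_cov_strength = 0.4, depth = 20000, seed = 9)
  frac <- relative_abundance(sim$counts)
  inj <- inject_crt_blooms(frac, n_crt = 2, baseline = 0.001, peak = 0.3,
                           duration_days = 4, seed = 9)
  rep_ <- detect_crt(inj$table)
  masked <- mask_crt_timepoints(inj$table, rep_)
  keep <- setdiff(inj$table$taxon_ids, rep_$taxon_id[rep_$is_crt])
  rho_all <- correlation_matrix(first_difference(inj$table))[keep, keep]
  # recompute on the masked table (gaps tolerated for this comparison)
  rho_masked <- suppressWarnings(
    correlation_matrix(first_difference(masked))[keep, keep])
  ut <- upper.tri(rho_all)
  fitlm <- stats::lm(rho_masked[ut] ~ rho_all[ut])
  expect_gt(summary(fitlm)$r.squared, 0.9)
})

test_that("bimodality moments agree with an independent implementation", {
  set.seed(13)
  x <- rgamma(400, 1.5)
  m <- length(x)
  g3 <- e1071::skewness(x, type = 2)
  g4 <- e1071::kurtosis(x, type = 2)
  expected <- (g3^2 + 1) / (g4 + 3 * (m - 1)^2 / ((m - 2) * (m - 3)))
  expect_equal(bimodality(x), expected, tolerance = 1e-12)
})
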