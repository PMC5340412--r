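test_that("model-corrected distances match closed forms", {
  p <- write_test_alignment(len = 300, n_diff = 30)
  jc <- pairwise_distance(p, model = "JC")
  expect_equal(jc["seqA", "seqC"], 0)
  expect_equal(jc["seqA", "seqB"], -3 / 4 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-6)
  # equal base frequencies: F84 collapses toward JC
  f84 <- pairwise_distance(p, model = "F84")
  expect_lt(abs(f84["seqA", "seqB"] - jc["seqA", "seqB"]), 0.01)
  expect_true(isSymmetric(jc))
})

test_that("PHYLIP square matrices round-trip through the reader", {
  d <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- tempfile()
  writeLines(c("3",
               paste("a", 0, 0.1, 0.2),
               paste("b", 0.1, 0, 0.3),
               paste("c", 0.2, 0.3, 0)), p)
  expect_equal(read_phylip_distances(p), d)
})

test_that("Spearman matrices are rank-invariant with flagged constants", {
  set.seed(3)
  M <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, letters[1:5]))
  rho <- correlation_matrix(M)
  expect_equal(diag(rho), setNames(rep(1, 5), letters[1:5]))
  M2 <- M
  M2[, 2] <- exp(M[, 2])          # monotone transform
  expect_equal(correlation_matrix(M2)[1, 2], rho[1, 2])
  # independent columns: small correlations
  expect_gte(mean(abs(rho[upper.tri(rho)]) < 0.2), 0.9)
  M3 <- cbind(M, const = 1)
  rho3 <- correlation_matrix(M3)
  expect_true(all(is.na(rho3["const", ])))
})

test_that("distance binning refines consistently and finds planted structure", {
  phy <- simulate_phylogeny(30, 5, seed = 4)
  set.seed(4)
  # clade-block innovations: close pairs correlated, distant pairs not
  S <- gutregimes:::clade_block_cov(phy$clades, 1, 0.5)
  X <- matrix(rnorm(200 * 30), 200) %*% chol(S)
  colnames(X) <- rownames(phy$dist)
  rho <- correlation_matrix(X)
  res <- bin_by_distance(rho, phy$dist, bin_width = 0.2)
  expect_lt(res$trend_rho, 0)
  expect_lt(res$trend_p_pairs, 0.001)
  expect_lte(res$mantel_p, 0.001)
  expect_equal(sum(res$bins$n_pairs), 30 * 29 / 2)
  # close pairs more correlated than distant ones
  expect_gt(res$bins$mean_coefficient[[1]],
            res$bins$mean_coefficient[[nrow(res$bins)]])
  # halving the width re-aggregates to the same coarse means
  fine <- bin_by_distance(rho, phy$dist, bin_width = 0.1, permutations = 0)
  coarse_from_fine <- fine$bins |>
    dplyr::mutate(cb = floor(bin_low / 0.2 + 1e-9)) |>
    dplyr::group_by(cb) |>
    dplyr::summarise(m = sum(mean_coefficient * n_pairs) / sum(n_pairs),
                     n = sum(n_pairs), .groups = "drop")
  expect_equal(coarse_from_fine$m, res$bins$mean_coefficient, tolerance = 1e-12)
  # label shuffle destroys the trend
  set.seed(5)
  sh <- sample(nrow(phy$dist))
  shuffled <- phy$dist[sh, sh]
  dimnames(shuffled) <- dimnames(phy$dist)
  null_res <- bin_by_distance(rho, shuffled, bin_width = 0.2, permutations = 199)
  expect_gt(null_res$mantel_p, 0.01)
})

test_that("coefficient coherence symmetrizes and handles empty support", {
  sim <- simulate_var_rates(12, 200, n_cross = 12, cross_coef = 0.3,
                            self_coef = 0.3, seed = 6)
  fit <- fit_svar(sim$rates, p = 1, seed = 6, check_stationarity = FALSE)
  phy <- simulate_phylogeny(12, 3, seed = 6)
  res <- coefficient_coherence(fit, phy$dist, bin_width = 0.3,
                               permutations = 0)
  # swapping taxon labels consistently leaves the binned result unchanged
  perm <- sample(12)
  fit2 <- fit
  fit2$coefficients <- lapply(fit$coefficients, function(m) {
    m2 <- m[perm, perm]
    dimnames(m2) <- dimnames(m)[1:2]
    dimnames(m2) <- list(fit$taxon_ids[perm], fit$taxon_ids[perm])
    m2
  })
  fit2$taxon_ids <- fit$taxon_ids[perm]
  res2 <- coefficient_coherence(fit2, phy$dist, bin_width = 0.3,
                                permutations = 0)
  expect_equal(dplyr::arrange(res2$bins, bin_low),
               dplyr::arrange(res$bins, bin_low), tolerance = 1e-12)
  # diagonal-only model: all off-diagonal coefficients zero
  diag_fit <- fit
  for (k in seq_along(diag_fit$coefficients)) {
    m <- diag_fit$coefficients[[k]]
    m[row(m) != col(m)] <- 0
    diag_fit$coefficients[[k]] <- m
  }
  res0 <- coefficient_coherence(diag_fit, phy$dist, bin_width = 0.3,
                                permutations = 0)
  expect_true(all(res0$bins$mean_coefficient == 0))
})
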