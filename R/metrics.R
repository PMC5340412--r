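# Internal benchmark metrics: each function regenerates its inputs from a
# seed, runs the package's own machinery, and measures the result. Used by
# the validation test suite and the reporting script.

#' @noRd
metric_test_calibration <- function(n_rep = 1000, m = 300, seed = 1) {
  with_seed(seed, {
    adf <- mean(vapply(seq_len(n_rep), function(i) {
      adf_test(cumsum(stats::rnorm(m)))$reject_unit_root
    }, logical(1)))
    kpss <- mean(vapply(seq_len(n_rep), function(i) {
      kpss_test(stats::rnorm(m), "level")$reject_stationarity
    }, logical(1)))
    list(adf_size_pct = 100 * adf, kpss_level_size_pct = 100 * kpss)
  })
}

#' @noRd
metric_mean_reversion <- function(phis = seq(0.1, 0.9, by = 0.1), m = 5000,
                                  seed = 1) {
  with_seed(seed, {
    err <- vapply(phis, function(phi) {
      x <- as.numeric(stats::arima.sim(list(ar = phi), m))
      tab <- otu_table(matrix(x - min(x) + 0.01, 1, m), "t1", seq_len(m))
      abs(mean_reversion(tab)$r - (-sqrt((1 - phi) / 2)))
    }, numeric(1))
    list(max_abs_error = max(err), errors = err)
  })
}

#' @noRd
metric_svar_recovery <- function(n_seeds = 20, seed = 1) {
  stats_ <- vapply(seq_len(n_seeds), function(i) {
    s <- seed * 100L + i
    sim <- simulate_var_rates(10, 300, p = 1, n_cross = 20, cross_coef = 0.3,
                              innovation_sd = 0.1, seed = s)
    fit <- fit_svar(sim$rates, p = 1, seed = s, check_stationarity = FALSE)
    truth <- sim$truth$coefficients[[1]]
    est <- fit$coefficients[[1]]
    tp <- sum(truth != 0 & est != 0)
    fp <- sum(truth == 0 & est != 0)
    fn <- sum(truth != 0 & est == 0)
    det <- truth != 0 & est != 0
    c(f1 = 2 * tp / (2 * tp + fp + fn),
      sign = if (any(det)) mean(sign(est[det]) == sign(truth[det])) else NA)
  }, numeric(2))
  list(support_f1 = mean(stats_["f1", ]),
       sign_agreement_pct = 100 * mean(stats_["sign", ], na.rm = TRUE))
}

#' @noRd
metric_granger <- function(n_null = 60, n_power = 50, seed = 1) {
  n_sig <- 0L; n_pairs <- 0L
  for (i in seq_len(n_null)) {
    s <- seed * 100L + i
    sim <- simulate_var_rates(10, 300, p = 1, n_cross = 0, self_coef = 0.5,
                              seed = s)
    fit <- fit_svar(sim$rates, p = 1, seed = s, check_stationarity = FALSE)
    g <- granger_tests(fit, sim$rates)
    n_sig <- n_sig + sum(g$significant)
    n_pairs <- n_pairs + 90L
  }
  hits <- 0L
  for (i in seq_len(n_power)) {
    s <- seed * 1000L + i
    sim <- simulate_var_rates(10, 300, p = 1, n_cross = 1, cross_coef = 0.4,
                              self_coef = 0.5, seed = s)
    truth <- sim$truth$coefficients[[1]]
    pos <- which(truth != 0 & row(truth) != col(truth), arr.ind = TRUE)
    fit <- fit_svar(sim$rates, p = 1, seed = s, check_stationarity = FALSE)
    g <- granger_tests(fit, sim$rates)
    hits <- hits + any(g$significant &
                         g$source == fit$taxon_ids[pos[1, 2]] &
                         g$target == fit$taxon_ids[pos[1, 1]])
  }
  list(null_false_edge_rate = n_sig / n_pairs,
       planted_edge_power_pct = 100 * hits / n_power)
}

#' @noRd
metric_dmm_recovery <- function(n_seeds = 20, seed = 1) {
  k3 <- vapply(seq_len(n_seeds), function(i) {
    s <- seed * 100L + i
    sim <- simulate_dmm(30, c(100, 100, 100), depth = 1000, seed = s)
    select_k(sim$counts, 4, seed = s)$best_k
  }, integer(1))
  k1 <- vapply(seq_len(n_seeds), function(i) {
    s <- seed * 200L + i
    sim <- simulate_dmm(30, 150, depth = 1000, seed = s)
    select_k(sim$counts, 3, seed = s)$best_k
  }, integer(1))
  list(k3_recovery_pct = 100 * mean(k3 == 3),
       k1_recovery_pct = 100 * mean(k1 == 1))
}

#' @noRd
metric_state_decay <- function(seed = 1) {
  a <- matrix(0.05, 30, 3)
  a[1:10, 1] <- 5; a[11:20, 2] <- 5; a[21:30, 3] <- 5
  tabs <- lapply(1:3, function(k) {
    simulate_dmm(30, 60, alphas = a[, k, drop = FALSE], depth = 1000,
                 seed = seed * 10L + k)$counts
  })
  names(tabs) <- paste0("subject", 1:3)
  dec <- state_decay(tabs, max_stride = 3, k_max = 5, seed = seed)
  purity <- dec$sharing |>
    dplyr::group_by(.data$stride, .data$state) |>
    dplyr::summarise(n_subj = dplyr::n(), .groups = "drop")
  list(plateau_k = as.numeric(names(sort(table(dec$curve$best_k),
                                         decreasing = TRUE))[1]),
       strides_at_plateau_pct = 100 * mean(dec$curve$best_k == 3),
       subject_pure = all(purity$n_subj == 1))
}

#' @noRd
metric_crt <- function(seed = 1) {
  sim <- simulate_svar_counts(n_taxa = 50, n_days = 200, ar_strength = 0.2,
                              clade_cov_strength = 0.3, depth = 10000,
                              seed = seed)
  frac <- relative_abundance(sim$counts)
  inj <- inject_crt_blooms(frac, n_crt = 5, baseline = 0.001, peak = 0.3,
                           duration_days = 5, seed = seed)
  rep_ <- detect_crt(inj$table)
  planted <- unique(inj$schedule$taxon_id)
  flagged <- rep_$taxon_id[rep_$is_crt]
  b_lim <- with_seed(seed, {
    c(uniform = bimodality(stats::runif(1e5)),
      normal = bimodality(stats::rnorm(1e5)))
  })
  list(precision = length(intersect(flagged, planted)) /
         max(length(flagged), 1),
       recall = length(intersect(flagged, planted)) / length(planted),
       b_uniform = unname(b_lim["uniform"]),
       b_normal = unname(b_lim["normal"]))
}

#' @noRd
metric_two_regime <- function(n_seeds = 20, seed = 1) {
  res <- vapply(seq_len(n_seeds), function(i) {
    s <- seed * 100L + i
    sim <- simulate_svar_counts(n_taxa = 50, n_days = 300, p = 1,
                                sparsity = 0.04, ar_strength = 0.4,
                                clade_cov_strength = 0.5, n_clades = 5,
                                depth = 10000, seed = s)
    rates <- first_difference(relative_abundance(sim$counts))
    fit <- fit_svar(rates, p = 1, seed = s, check_stationarity = FALSE)
    # Mantel permutations draw from the RNG: seed them for reproducibility
    with_seed(s + 7L, {
      resid_coh <- bin_by_distance(correlation_matrix(fit$residuals),
                                   sim$truth$phylogeny)
      coef_coh <- coefficient_coherence(fit, sim$truth$phylogeny)
      # coherence = related taxa positively coupled: a negative distance
      # trend significant at the Mantel p <= 0.001 level, judged with the
      # same yardstick on both matrices. (At looser levels the elastic
      # net's grouping effect leaves a faint coefficient trend in some
      # runs; see the methods vignette.)
      c(resid_sig = resid_coh$mantel_p <= 0.001 && resid_coh$trend_rho < 0,
        coef_none = is.na(coef_coh$mantel_p) || coef_coh$trend_rho >= 0 ||
          coef_coh$mantel_p > 0.001)
    })
  }, logical(2))
  list(residual_trend_detected_pct = 100 * mean(res["resid_sig", ]),
       coefficient_trend_absent_pct = 100 * mean(res["coef_none", ]))
}

#' @noRd
metric_delta_pattern <- function(seed = 1) {
  tab <- with_seed(seed, {
    vals <- t(vapply(seq_len(50), function(i) {
      pmax(0.02 + 0.005 * as.numeric(stats::arima.sim(list(ar = 0.3), 300)), 0)
    }, numeric(300)))
    otu_table(vals, sprintf("t%02d", seq_len(50)), seq_len(300))
  })
  st <- stationarity_table(list(synthetic = tab))
  delta <- st[st$series == "delta", ]
  list(adf_pass_pct = delta$adf,
       kpss_trend_pass_pct = delta$kpss_trend,
       kpss_level_pass_pct = delta$kpss_level)
}
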