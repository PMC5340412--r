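test_that("lagged design aligns responses with strictly earlier predictors", {
  sim <- simulate_var_rates(2, 5, n_cross = 0, self_coef = 0.2, seed = 1)
  rm5 <- rate_matrix(sim$rates$values[1:5, ], sim$rates$taxon_ids, 1:5, 2:6)
  expect_error(build_design(rm5, 1), "at least")
  sim <- simulate_var_rates(2, 15, n_cross = 0, self_coef = 0.2, seed = 1)
  des <- build_design(sim$rates, 1)
  expect_equal(dim(des$response), c(14L, 2L))
  expect_equal(dim(des$predictors), c(14L, 2L))
  # predictor row t equals the rate row immediately before response row t
  expect_equal(unname(des$predictors[3, ]), unname(sim$rates$values[3, ]))
  expect_equal(unname(des$response[3, ]), unname(sim$rates$values[4, ]))
  des3 <- build_design(simulate_var_rates(4, 40, n_cross = 0, self_coef = 0.2,
                                          seed = 2)$rates, 3)
  expect_equal(ncol(des3$predictors), 12L)
})

test_that("planted sparse VAR support and signs are recovered", {
  stats <- vapply(1:3, function(seed) {
    sim <- simulate_var_rates(10, 300, p = 1, n_cross = 20, cross_coef = 0.3,
                              innovation_sd = 0.1, seed = seed)
    fit <- fit_svar(sim$rates, p = 1, seed = seed, check_stationarity = FALSE)
    truth <- sim$truth$coefficients[[1]]
    est <- fit$coefficients[[1]]
    tp <- sum(truth != 0 & est != 0)
    fp <- sum(truth == 0 & est != 0)
    fn <- sum(truth != 0 & est == 0)
    det <- truth != 0 & est != 0
    c(f1 = 2 * tp / (2 * tp + fp + fn),
      sign = mean(sign(est[det]) == sign(truth[det])))
  }, numeric(2))
  expect_gte(mean(stats["f1", ]), 0.75)
  expect_gte(mean(stats["sign", ]), 0.95)
})

test_that("independent AR(1) taxa yield an essentially diagonal model", {
  sim <- simulate_var_rates(10, 300, n_cross = 0, self_coef = 0.5, seed = 21)
  fit <- fit_svar(sim$rates, p = 1, seed = 21, check_stationarity = FALSE)
  offdiag <- fit$coefficients[[1]]
  diag(offdiag) <- 0
  expect_lte(sum(offdiag != 0) / 90, 0.05)
  # residual autocorrelation reduced relative to the input rates
  ac_in <- apply(sim$rates$values, 2, function(x) abs(acf(x, 1, plot = FALSE)$acf[2]))
  ac_out <- apply(fit$residuals, 2, function(x) abs(acf(x, 1, plot = FALSE)$acf[2]))
  expect_gte(mean(ac_out < ac_in[colnames(fit$residuals)]), 0.9)
})

test_that("variance explained behaves as a clipped R-squared", {
  sim <- simulate_var_rates(8, 200, n_cross = 0, self_coef = 0, seed = 31)
  fit <- fit_svar(sim$rates, p = 1, seed = 31, check_stationarity = FALSE)
  ve <- variance_explained(fit)
  expect_true(all(ve$r_squared >= 0 & ve$r_squared <= 1))
  expect_lte(median(ve$r_squared), 0.05)   # pure-noise rates: null model
  # near-noise-free synthetic VAR: most variance captured
  strong <- simulate_var_rates(6, 400, n_cross = 6, cross_coef = 0.3,
                               self_coef = 0.6, innovation_sd = 0.01, seed = 32)
  # inflate signal variance relative to innovations via strong self terms
  sfit <- fit_svar(strong$rates, p = 1, seed = 32, check_stationarity = FALSE)
  expect_gte(median(variance_explained(sfit)$r_squared), 0.3)
  # scale invariance of R^2
  scaled <- strong$rates
  scaled$values[, 1] <- scaled$values[, 1] * 7
  sfit2 <- fit_svar(scaled, p = 1, seed = 32, check_stationarity = FALSE)
  expect_equal(sfit2$r_squared[[1]], sfit$r_squared[[1]], tolerance = 1e-6)
})

test_that("fit is deterministic and refitting residuals finds no structure", {
  sim <- simulate_var_rates(8, 250, n_cross = 10, cross_coef = 0.3,
                            self_coef = 0.3, seed = 41)
  f1 <- fit_svar(sim$rates, p = 1, seed = 41, check_stationarity = FALSE)
  f2 <- fit_svar(sim$rates, p = 1, seed = 41, check_stationarity = FALSE)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$residuals, f2$residuals)
  resid_rm <- rate_matrix(f1$residuals, f1$taxon_ids,
                          seq_len(nrow(f1$residuals)),
                          seq_len(nrow(f1$residuals)) + 1)
  rfit <- fit_svar(resid_rm, p = 1, seed = 41, check_stationarity = FALSE)
  expect_gte(mean(rfit$r_squared <= 0.05), 0.9)
  # stability of accepted fits on stationary data
  expect_lt(companion_spectral_radius(f1$coefficients), 1)
})

test_that("coefficient error on the true support shrinks with series length", {
  rmse_at <- function(Tlen) {
    mean(vapply(1:3, function(seed) {
      sim <- simulate_var_rates(10, Tlen, n_cross = 20, cross_coef = 0.3,
                                innovation_sd = 0.1, seed = 50 + seed)
      fit <- fit_svar(sim$rates, p = 1, seed = seed, check_stationarity = FALSE)
      truth <- sim$truth$coefficients[[1]]
      sqrt(mean((fit$coefficients[[1]][truth != 0] - truth[truth != 0])^2))
    }, numeric(1)))
  }
  errs <- c(rmse_at(100), rmse_at(300), rmse_at(1000))
  expect_true(all(diff(errs) < 0))
})

test_that("Granger edges require support and detect planted interactions", {
  # empty off-diagonal support: no edges
  sim0 <- simulate_var_rates(6, 200, n_cross = 0, self_coef = 0.5, seed = 61)
  fit0 <- fit_svar(sim0$rates, p = 1, seed = 61, check_stationarity = FALSE)
  for (k in seq_len(fit0$p)) {
    offd <- fit0$coefficients[[k]]; diag(offd) <- 0
    fit0$coefficients[[k]][offd != 0] <- 0
  }
  g0 <- granger_tests(fit0, sim0$rates)
  expect_equal(nrow(g0), 0L)
  # planted strong edge is found significant
  sim <- simulate_var_rates(10, 300, n_cross = 1, cross_coef = 0.4,
                            self_coef = 0.5, seed = 62)
  truth <- sim$truth$coefficients[[1]]
  pos <- which(truth != 0 & row(truth) != col(truth), arr.ind = TRUE)
  fit <- fit_svar(sim$rates, p = 1, seed = 62, check_stationarity = FALSE)
  g <- granger_tests(fit, sim$rates)
  hit <- any(g$significant &
               g$source == fit$taxon_ids[pos[1, 2]] &
               g$target == fit$taxon_ids[pos[1, 1]])
  expect_true(hit)
  expect_true(all(g$df >= 1))
  expect_true(all(g$p_value >= 0 & g$p_value <= 1))
})

test_that("tidy and glance summarize a fit coherently", {
  sim <- simulate_var_rates(6, 150, n_cross = 6, cross_coef = 0.3,
                            self_coef = 0.3, seed = 71)
  fit <- fit_svar(sim$rates, p = 1, seed = 71, check_stationarity = FALSE)
  td <- tidy(fit)
  expect_true(all(td$estimate != 0))
  expect_equal(nrow(tidy(fit, all = TRUE)), 36L)
  gl <- glance(fit)
  expect_equal(gl$n_nonzero, nrow(td))
  expect_equal(gl$p, 1L)
})
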