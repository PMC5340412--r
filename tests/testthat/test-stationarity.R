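test_that("sample ACF has unit lag zero and matches AR(1) decay", {
  set.seed(5)
  cg <- acf_correlogram(rnorm(100), max_lag = 10)
  expect_equal(cg$acf[[1]], 1)
  expect_true(all(abs(cg$acf) <= 1))
  expect_error(acf_correlogram(rep(2, 50), 5), "constant")

  ar <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  cga <- acf_correlogram(ar, max_lag = 5)
  expect_true(all(abs(cga$acf[2:6] - 0.8^(1:5)) < 0.05))

  wn <- acf_correlogram(rnorm(500), max_lag = 50)
  inside <- mean(abs(wn$acf[-1]) < attr(wn, "ci_halfwidth"))
  expect_gte(inside, 0.86)
})

test_that("ADF separates stationary from unit-root series", {
  set.seed(6)
  # iid noise: overwhelming rejection of the unit root
  rej_iid <- mean(replicate(150, adf_test(rnorm(300))$reject_unit_root))
  expect_gte(rej_iid, 0.95)
  # random walk: rejection near the nominal level
  rej_rw <- mean(replicate(300, adf_test(cumsum(rnorm(300)))$reject_unit_root))
  expect_lt(rej_rw, 0.12)
  # differenced random walk: stationary again
  rej_d <- mean(replicate(100, adf_test(diff(cumsum(rnorm(301))))$reject_unit_root))
  expect_gte(rej_d, 0.95)
  expect_error(adf_test(rep(1, 50)), "constant")
})

test_that("KPSS level and trend modes behave as their nulls dictate", {
  set.seed(7)
  # iid noise: level-stationarity retained near nominal rate
  rej_iid <- mean(replicate(300, kpss_test(rnorm(300), "level")$reject_stationarity))
  expect_lt(rej_iid, 0.11)
  # random walk: strong rejection
  rej_rw <- mean(replicate(100, kpss_test(cumsum(rnorm(300)), "level")$reject_stationarity))
  expect_gte(rej_rw, 0.90)
  # linear trend + noise: trend mode retains, level mode rejects
  trend_series <- function() 0.05 * seq_len(300) + rnorm(300)
  keep_trend <- mean(replicate(100, !kpss_test(trend_series(), "trend")$reject_stationarity))
  rej_level <- mean(replicate(100, kpss_test(trend_series(), "level")$reject_stationarity))
  expect_gte(keep_trend, 0.85)
  expect_gte(rej_level, 0.90)
  # constant series: statistic 0, never rejects
  k0 <- kpss_test(rep(3, 50), "level")
  expect_equal(k0$statistic, 0)
  expect_false(k0$reject_stationarity)
})

test_that("mean reversion matches the AR(1) closed form", {
  set.seed(8)
  m <- 5000
  mk <- function(phi) {
    x <- if (phi == 0) rnorm(m) else as.numeric(arima.sim(list(ar = phi), m))
    otu_table(matrix(x - min(x) + 0.01, 1, m), "t1", seq_len(m))
  }
  for (phi in c(0, 0.5)) {
    r <- mean_reversion(mk(phi))$r
    expect_lt(abs(r - (-sqrt((1 - phi) / 2))), 0.05)
  }
  rw <- cumsum(rnorm(m))
  tab <- otu_table(matrix(rw - min(rw) + 1, 1, m), "t1", seq_len(m))
  expect_lt(abs(mean_reversion(tab)$r), 0.06)
  # constant taxon flagged undefined
  const <- otu_table(matrix(c(rep(1, 12), abs(rnorm(12)) + 1), 2, 12,
                            byrow = TRUE),
                     c("a", "b"), 1:12)
  mr <- mean_reversion(const)
  expect_false(mr$defined[[1]])
  expect_true(mr$defined[[2]])
})

test_that("differenced mean-reverting taxa pass all three tests", {
  st <- stationarity_table(list(x = ar1_table(n = 20, m = 300, seed = 11)))
  delta <- st[st$series == "delta", ]
  expect_equal(delta$adf, 100)
  expect_equal(delta$kpss_trend, 100)
  expect_equal(delta$kpss_level, 100)
  # raw random walks mostly fail KPSS level
  set.seed(12)
  rw_vals <- t(vapply(1:15, function(i) cumsum(rnorm(300)), numeric(300)))
  rw_tab <- otu_table(rw_vals - min(rw_vals) + 1, sprintf("w%02d", 1:15), 1:300)
  raw <- stationarity_table(list(w = rw_tab))
  expect_lt(raw[raw$series == "raw", ]$kpss_level, 15)
})
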