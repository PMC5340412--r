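#' Sample autocorrelation function of a series
#'
#' Standard sample ACF: global mean, biased (1/m) denominator. Also returns
#' the Bartlett white-noise band half-width `1.96 / sqrt(m)`.
#'
#' @param series Numeric vector, length > `max_lag`, non-constant.
#' @param max_lag Largest lag (days) to evaluate.
#' @return A tibble of class `correlogram` with columns `lag`, `acf` and an
#'   attribute `ci_halfwidth`.
#' @export
acf_correlogram <- function(series, max_lag) {
  series <- as.numeric(series)
  m <- length(series)
  if (max_lag < 1 || m <= max_lag) stop("need length(series) > max_lag >= 1")
  if (any(!is.finite(series))) stop("series contains non-finite values")
  if (stats::var(series) == 0) stop("ACF undefined for a constant series")
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  out <- tibble::tibble(lag = 0:max_lag, acf = as.vector(a$acf))
  attr(out, "ci_halfwidth") <- 1.96 / sqrt(m)
  class(out) <- c("correlogram", class(out))
  out
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression of `diff(y)` on `y[t-1]`, lagged differences, and an intercept
#' (optionally a linear trend). The augmentation order is chosen by AIC over
#' `0..floor(12 * (m/100)^0.25)` on a common estimation sample. The null
#' hypothesis is a unit root; small p-values favour stationarity. P-values
#' interpolate Monte-Carlo quantiles of the Dickey-Fuller tau distribution.
#'
#' @param series Numeric vector, length >= 20.
#' @param alpha Significance level (default 0.05).
#' @param trend Include a linear trend in the test regression (default FALSE:
#'   abundance series fluctuate around a level, not a trend).
#' @return A list with `statistic`, `p_value`, `lag_order`,
#'   `reject_unit_root`, `alpha`.
#' @export
adf_test <- function(series, alpha = 0.05, trend = FALSE) {
  y <- as.numeric(series)
  m <- length(y)
  if (m < 20) stop("need at least 20 observations")
  if (any(!is.finite(y))) stop("series contains non-finite values")
  if (stats::var(y) == 0) stop("ADF undefined for a constant series")
  kmax <- floor(12 * (m / 100)^0.25)
  kmax <- min(kmax, m - 12)  # keep enough residual df
  dy <- diff(y)
  # selection on the common sample t = kmax+1 .. m-1 (rows of dy)
  sel_rows <- (kmax + 1):length(dy)
  aic_k <- vapply(0:kmax, function(k) {
    fit <- adf_ols(y, dy, k, rows = sel_rows, trend = trend)
    n <- length(sel_rows)
    n * log(fit$rss / n) + 2 * (fit$df_model)
  }, numeric(1))
  k <- (0:kmax)[which.min(aic_k)]
  fit <- adf_ols(y, dy, k, rows = (k + 1):length(dy), trend = trend)
  tau <- fit$tau
  p <- df_pvalue(tau, trend)
  list(statistic = tau, p_value = p, lag_order = k,
       reject_unit_root = p < alpha, alpha = alpha)
}

# OLS for the ADF regression at augmentation order k, on selected rows of dy
adf_ols <- function(y, dy, k, rows, trend) {
  X <- cbind(intercept = 1, ylag = y[rows])
  if (trend) X <- cbind(X, trend = rows)
  if (k > 0) {
    lagged <- vapply(seq_len(k), function(j) dy[rows - j], numeric(length(rows)))
    X <- cbind(X, lagged)
  }
  resp <- dy[rows]
  qr_ <- qr(X)
  beta <- qr.coef(qr_, resp)
  res <- resp - X %*% beta
  rss <- sum(res^2)
  s2 <- rss / (length(rows) - ncol(X))
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(s2 * XtXinv[2, 2])
  list(tau = beta[["ylag"]] / se, rss = rss, df_model = ncol(X))
}

df_pvalue <- function(tau, trend) {
  qs <- if (trend) .df_tau_ct else .df_tau_c
  if (tau <= qs[[1]]) return(0.001)
  if (tau >= qs[[length(qs)]]) return(0.999)
  stats::approx(qs, .df_probs, xout = tau, ties = "ordered")$y
}

# KPSS critical values (eta statistic), upper-tail levels 10/5/2.5/1 %
.kpss_cv <- list(
  level = c(`0.10` = 0.347, `0.05` = 0.463, `0.025` = 0.574, `0.01` = 0.739),
  trend = c(`0.10` = 0.119, `0.05` = 0.146, `0.025` = 0.176, `0.01` = 0.216)
)

#' KPSS stationarity test
#'
#' Null hypothesis: the series is (level- or trend-) stationary. The eta
#' statistic uses a Newey-West long-run variance with Bartlett weights and
#' bandwidth `floor(4 * (m/100)^0.25)`, compared to the published
#' critical-value table. A constant series yields statistic 0 and never
#' rejects.
#'
#' @param series Numeric vector, length >= 20.
#' @param mode `"level"` or `"trend"`.
#' @param alpha Significance level, one of 0.10, 0.05, 0.025, 0.01.
#' @return A list with `statistic`, `p_value` (interpolated between table
#'   rows, clipped to \[0.01, 0.10\]), `reject_stationarity`, `mode`, `alpha`.
#' @export
kpss_test <- function(series, mode = c("level", "trend"), alpha = 0.05) {
  mode <- match.arg(mode)
  y <- as.numeric(series)
  m <- length(y)
  if (m < 20) stop("need at least 20 observations")
  if (any(!is.finite(y))) stop("series contains non-finite values")
  cv <- .kpss_cv[[mode]]
  if (!as.character(alpha) %in% names(cv)) {
    stop("alpha must be one of 0.10, 0.05, 0.025, 0.01")
  }
  if (stats::var(y) == 0) {
    return(list(statistic = 0, p_value = 0.10, reject_stationarity = FALSE,
                mode = mode, alpha = alpha))
  }
  e <- if (mode == "level") y - mean(y) else stats::lm.fit(cbind(1, seq_len(m)), y)$residuals
  S <- cumsum(e)
  l <- floor(4 * (m / 100)^0.25)
  s2 <- sum(e^2) / m
  if (l > 0) {
    for (j in seq_len(l)) {
      w <- 1 - j / (l + 1)
      s2 <- s2 + 2 * w * sum(e[(j + 1):m] * e[1:(m - j)]) / m
    }
  }
  stat <- sum(S^2) / (m^2 * s2)
  levels <- as.numeric(names(cv))
  p <- if (stat <= min(cv)) 0.10 else if (stat >= max(cv)) 0.01 else {
    stats::approx(cv, levels, xout = stat, ties = "ordered")$y
  }
  list(statistic = stat, p_value = p,
       reject_stationarity = stat > cv[[as.character(alpha)]],
       mode = mode, alpha = alpha)
}

#' Combined stationarity verdict for one series
#'
#' A series is called stationary when the ADF test rejects its unit-root
#' null AND the KPSS level test fails to reject its stationarity null, both
#' at `alpha`. The KPSS trend variant is reported alongside.
#'
#' @param series Numeric vector.
#' @param alpha Significance level.
#' @return A list with `adf`, `kpss_level`, `kpss_trend`, and `stationary`.
#' @export
stationarity_verdict <- function(series, alpha = 0.05) {
  adf <- adf_test(series, alpha = alpha)
  kl <- kpss_test(series, "level", alpha = alpha)
  kt <- kpss_test(series, "trend", alpha = alpha)
  list(adf = adf, kpss_level = kl, kpss_trend = kt,
       stationary = adf$reject_unit_root && !kl$reject_stationarity)
}

#' Stationarity summary table across datasets
#'
#' For each dataset, the percentage of taxa passing each test — ADF: rejects
#' the unit root; KPSS (trend/level): fails to reject stationarity — on the
#' raw per-taxon series and on the first-differenced (delta) series.
#'
#' @param tables Named list of `otu_table`s (already reduced to the taxa of
#'   interest, e.g. via [top_taxa()]).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with columns `dataset`, `series` (raw/delta), `adf`,
#'   `kpss_trend`, `kpss_level` — percentages rounded to one decimal.
#' @export
stationarity_table <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  one <- function(mat) {
    res <- apply(mat, 2, function(s) {
      if (stats::var(s) == 0) return(c(NA, NA, NA))
      c(adf_test(s, alpha)$reject_unit_root,
        !kpss_test(s, "trend", alpha)$reject_stationarity,
        !kpss_test(s, "level", alpha)$reject_stationarity)
    })
    round(100 * rowMeans(res, na.rm = TRUE), 1)
  }
  purrr::map_dfr(names(tables), function(nm) {
    tab <- tables[[nm]]
    raw <- one(t(tab$values))
    delta <- one(first_difference(tab)$values)
    tibble::tibble(
      dataset = nm, series = c("raw", "delta"),
      adf = c(raw[1], delta[1]),
      kpss_trend = c(raw[2], delta[2]),
      kpss_level = c(raw[3], delta[3])
    )
  })
}

#' Mean reversion of taxon trajectories
#'
#' Per taxon, ordinary least squares of the one-step change
#' `X(t+1) - X(t)` on the current level `X(t)`; the Pearson correlation `r`
#' of that regression is the restoring-force summary. Mean-reverting taxa
#' give negative `r` (for an AR(1) with coefficient `phi`,
#' `r = -sqrt((1 - phi) / 2)`); random walks give about 0.
#'
#' @param table An `otu_table` with >= 10 samples.
#' @return A tibble with columns `taxon_id`, `r`, `slope`, `p_value`,
#'   `defined` (FALSE for constant taxa, which are excluded from summaries).
#' @export
mean_reversion <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (n_samples(table) < 10) stop("need at least 10 samples")
  purrr::map_dfr(seq_len(n_taxa(table)), function(i) {
    x <- table$values[i, ]
    lvl <- x[-length(x)]
    dx <- diff(x)
    if (stats::var(lvl) == 0 || stats::var(dx) == 0) {
      return(tibble::tibble(taxon_id = table$taxon_ids[i], r = NA_real_,
                            slope = NA_real_, p_value = NA_real_,
                            defined = FALSE))
    }
    fit <- stats::lm(dx ~ lvl)
    ct <- stats::cor.test(lvl, dx)
    tibble::tibble(taxon_id = table$taxon_ids[i],
                   r = unname(ct$estimate),
                   slope = unname(stats::coef(fit)[2]),
                   p_value = ct$p.value, defined = TRUE)
  })
}
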