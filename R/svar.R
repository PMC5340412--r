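#' Lagged design matrices for a VAR(p) fit
#'
#' Aligns response rows `t = p+1 .. M` of a rate matrix with predictor rows
#' `[X(t-1), ..., X(t-p)]`. Predictor columns are grouped by lag (all taxa
#' at lag 1, then lag 2, ...), named `"<taxon>.lag<k>"`; this order is the
#' package-wide convention. No predictor row ever contains same-interval
#' response values.
#'
#' @param rates A [rate_matrix()] with at least `p + 10` rows.
#' @param p Lag order.
#' @return A list with `response` (`(M - p) x n`), `predictors`
#'   (`(M - p) x (n * p)`), `p`, `taxon_ids`.
#' @export
build_design <- function(rates, p) {
  stopifnot(inherits(rates, "rate_matrix"))
  if (p < 1 || p != round(p)) stop("`p` must be a positive integer")
  M <- nrow(rates$values)
  if (M < p + 10) {
    stop(sprintf("rate matrix has %d rows; need at least %d for p = %d",
                 M, p + 10, p))
  }
  n <- ncol(rates$values)
  rows <- (p + 1):M
  response <- rates$values[rows, , drop = FALSE]
  predictors <- do.call(cbind, lapply(seq_len(p), function(k) {
    blk <- rates$values[rows - k, , drop = FALSE]
    colnames(blk) <- paste0(rates$taxon_ids, ".lag", k)
    blk
  }))
  list(response = response, predictors = predictors, p = p,
       taxon_ids = rates$taxon_ids)
}

#' Fit a sparse VAR(p) by per-equation elastic net
#'
#' Each taxon's rate equation is regressed on all taxa's rates at lags
#' `1..p` with elastic-net regularization (mixing `l1_ratio`). The penalty
#' weight is chosen per equation by rolling-origin cross-validation: the
#' validation blocks are consecutive, time-ordered chunks at the end of the
#' series and training always precedes validation. Coefficients whose
#' standardized magnitude falls below `threshold` are set to exactly zero;
#' remaining coefficients are reported on the original scale. Residuals and
#' per-taxon variance explained come from the thresholded model.
#'
#' @param rates A [rate_matrix()].
#' @param p Lag order (default 3: autocorrelation in daily gut series is
#'   largely gone after 3-4 days).
#' @param l1_ratio Elastic-net mixing in (0, 1]; 1 = lasso (default 0.5).
#' @param n_lambda Size of the log-spaced penalty grid (default 50).
#' @param threshold Standardized-coefficient floor below which estimates
#'   are zeroed (default 1e-3).
#' @param seed Integer seed recorded in the fit metadata.
#' @param n_folds Number of rolling-origin validation blocks (default 5).
#' @param check_stationarity Screen each taxon with the combined ADF/KPSS
#'   verdict and warn on failures (default TRUE).
#' @return An object of class `svar_fit`: `p`, `intercepts`, `coefficients`
#'   (list of `p` matrices, entry `[i, j]` = effect of taxon `j` at that lag
#'   on taxon `i`), `residuals`, `r_squared`, `fit_meta`.
#' @export
fit_svar <- function(rates, p = 3, l1_ratio = 0.5, n_lambda = 50,
                     threshold = 1e-3, seed = 1, n_folds = 5,
                     check_stationarity = TRUE) {
  stopifnot(inherits(rates, "rate_matrix"))
  if (l1_ratio <= 0 || l1_ratio > 1) stop("`l1_ratio` must be in (0, 1]")
  if (any(!is.finite(rates$values))) stop("rate matrix contains non-finite values")
  des <- build_design(rates, p)
  Y <- des$response
  X <- des$predictors
  n <- ncol(Y)
  N <- nrow(Y)
  if (check_stationarity && nrow(rates$values) >= 20) {
    ok <- vapply(seq_len(n), function(i) {
      s <- rates$values[, i]
      if (stats::var(s) == 0) return(FALSE)
      stationarity_verdict(s)$stationary
    }, logical(1))
    if (!all(ok)) {
      warning(sprintf("%d taxa fail the combined stationarity verdict: %s",
                      sum(!ok),
                      paste(utils::head(des$taxon_ids[!ok], 5), collapse = ", ")))
    }
  }
  sd_x <- apply(X, 2, stats::sd)
  mu_x <- colMeans(X)
  live <- sd_x > 0
  Xs <- sweep(sweep(X[, live, drop = FALSE], 2, mu_x[live]), 2, sd_x[live], "/")
  folds <- rolling_folds(N, n_folds)
  intercepts <- numeric(n)
  coefs <- lapply(seq_len(p), function(k) {
    matrix(0, n, n, dimnames = list(des$taxon_ids, des$taxon_ids))
  })
  residuals <- matrix(NA_real_, N, n, dimnames = list(NULL, des$taxon_ids))
  r2 <- rep(NA_real_, n)
  lambdas <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- Y[, i]
    sd_y <- stats::sd(y)
    if (sd_y == 0) {
      residuals[, i] <- 0
      intercepts[i] <- y[1]
      next
    }
    ys <- (y - mean(y)) / sd_y
    path <- glmnet::glmnet(Xs, ys, alpha = l1_ratio, nlambda = n_lambda,
                           standardize = FALSE, intercept = FALSE)
    grid <- path$lambda
    cv_mse <- matrix(NA_real_, length(folds), length(grid))
    for (f in seq_along(folds)) {
      tr <- folds[[f]]$train; va <- folds[[f]]$validate
      fit_f <- glmnet::glmnet(Xs[tr, , drop = FALSE], ys[tr], alpha = l1_ratio,
                              lambda = grid, standardize = FALSE,
                              intercept = FALSE)
      pred <- stats::predict(fit_f, Xs[va, , drop = FALSE], s = grid)
      cv_mse[f, ] <- colMeans((pred - ys[va])^2)
    }
    mse <- colMeans(cv_mse, na.rm = TRUE)
    cv_se <- apply(cv_mse, 2, stats::sd) / sqrt(nrow(cv_mse))
    # one-standard-error rule: the sparsest model whose validation error is
    # within one SE of the minimum (favors support recovery over raw MSE)
    lam <- max(grid[mse <= min(mse) + cv_se[which.min(mse)]])
    lambdas[i] <- lam
    beta_std <- as.numeric(stats::coef(path, s = lam, exact = FALSE))[-1]
    beta_std[abs(beta_std) < threshold] <- 0
    beta <- numeric(ncol(X))
    beta[live] <- beta_std * sd_y / sd_x[live]
    q <- mean(y) - sum(beta * mu_x)
    fitted <- as.numeric(X %*% beta) + q
    e <- y - fitted
    residuals[, i] <- e
    intercepts[i] <- q
    r2[i] <- max(0, min(1, 1 - stats::var(e) / stats::var(y)))
    for (k in seq_len(p)) {
      coefs[[k]][i, ] <- beta[((k - 1) * n + 1):(k * n)]
    }
  }
  names(intercepts) <- des$taxon_ids
  names(r2) <- des$taxon_ids
  structure(
    list(p = p, taxon_ids = des$taxon_ids, intercepts = intercepts,
         coefficients = coefs, residuals = residuals, r_squared = r2,
         design = des,
         fit_meta = list(l1_ratio = l1_ratio, n_lambda = n_lambda,
                         threshold = threshold, seed = seed,
                         n_folds = n_folds, lambda = lambdas)),
    class = "svar_fit"
  )
}

# time-ordered expanding-window folds: validation blocks tile the last half
rolling_folds <- function(N, n_folds) {
  h <- max(2, floor(N / (2 * n_folds)))
  starts <- N - n_folds * h + h * (0:(n_folds - 1))
  if (starts[[1]] < 10) stop("too few rows for rolling-origin validation")
  lapply(starts, function(s) {
    list(train = seq_len(s), validate = (s + 1):(s + h))
  })
}

#' @export
print.svar_fit <- function(x, ...) {
  nz <- sum(vapply(x$coefficients, function(m) sum(m != 0), numeric(1)))
  cat(sprintf("<svar_fit> p = %d, %d taxa, %d obs, %d nonzero coefficients\n",
              x$p, length(x$taxon_ids), nrow(x$residuals), nz))
  invisible(x)
}

#' Per-taxon variance explained by an sVAR fit
#'
#' `R^2 = 1 - Var(residual) / Var(rate)`, clipped to \[0, 1\]. Taxa whose
#' rate series has zero variance are flagged undefined.
#'
#' @param model An `svar_fit`.
#' @return A tibble with columns `taxon_id`, `r_squared`, `defined`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "svar_fit"))
  tibble::tibble(taxon_id = model$taxon_ids,
                 r_squared = unname(model$r_squared),
                 defined = !is.na(model$r_squared))
}

#' Granger-causality tests on the sVAR support
#'
#' For each ordered taxon pair `j -> i` with at least one nonzero lag
#' coefficient in the fitted model, equation `i` is refit by ordinary least
#' squares restricted to its selected support, and a Wald chi-squared test
#' of the joint nullity of taxon `j`'s retained lag coefficients is
#' computed (`df` = number of retained lags). Self-loops are excluded.
#' This is a post-selection test: under a global null the realized
#' false-edge rate runs slightly above the nominal level.
#'
#' @param model An `svar_fit`.
#' @param rates The [rate_matrix()] the model was fit to.
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply Benjamini-Hochberg across edges before calling
#'   significance (default FALSE: raw p < alpha).
#' @return An object of class `granger_network`: a tibble of edges with
#'   columns `source`, `target`, `lags`, `coefficients` (list columns),
#'   `statistic`, `df`, `p_value`, `significant`; attribute `alpha`.
#' @export
granger_tests <- function(model, rates, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(model, "svar_fit"), inherits(rates, "rate_matrix"))
  des <- build_design(rates, model$p)
  X <- des$predictors
  Y <- des$response
  n <- length(model$taxon_ids)
  edges <- list()
  for (i in seq_len(n)) {
    sel <- unlist(lapply(seq_len(model$p), function(k) {
      which(model$coefficients[[k]][i, ] != 0) + (k - 1) * n
    }))
    if (length(sel) == 0) next
    if (length(sel) + 1 >= nrow(X)) {
      warning("support larger than sample size for taxon ",
              model$taxon_ids[i], "; equation skipped")
      next
    }
    Xi <- cbind(1, X[, sel, drop = FALSE])
    qr_ <- qr(Xi)
    beta <- qr.coef(qr_, Y[, i])
    res <- Y[, i] - Xi %*% beta
    s2 <- sum(res^2) / (nrow(Xi) - ncol(Xi))
    V <- chol2inv(qr.R(qr_)) * s2
    src_tax <- ((sel - 1) %% n) + 1
    src_lag <- ((sel - 1) %/% n) + 1
    for (j in setdiff(unique(src_tax), i)) {
      pos <- which(src_tax == j)
      b <- beta[pos + 1]
      Vb <- V[pos + 1, pos + 1, drop = FALSE]
      stat <- tryCatch(as.numeric(t(b) %*% solve(Vb, b)),
                       error = function(e) NA_real_)
      if (!is.finite(stat)) next
      edges[[length(edges) + 1]] <- tibble::tibble(
        source = model$taxon_ids[j], target = model$taxon_ids[i],
        lags = list(src_lag[pos]), coefficients = list(unname(b)),
        statistic = stat, df = length(pos),
        p_value = stats::pchisq(stat, df = length(pos), lower.tail = FALSE)
      )
    }
  }
  out <- if (length(edges) == 0) {
    tibble::tibble(source = character(), target = character(),
                   lags = list(), coefficients = list(),
                   statistic = numeric(), df = integer(),
                   p_value = numeric(), significant = logical())
  } else {
    e <- dplyr::bind_rows(edges)
    pv <- if (fdr) stats::p.adjust(e$p_value, "BH") else e$p_value
    e$significant <- pv < alpha
    e
  }
  attr(out, "alpha") <- alpha
  attr(out, "fdr") <- fdr
  class(out) <- c("granger_network", class(out))
  out
}

#' Spectral radius of a VAR coefficient set in companion form
#'
#' Below 1 means the implied VAR(p) process is stationary.
#'
#' @param coefficients A list of `p` square lag-coefficient matrices.
#' @return The largest eigenvalue modulus of the companion matrix.
#' @export
companion_spectral_radius <- function(coefficients) {
  p <- length(coefficients)
  n <- nrow(coefficients[[1]])
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) {
    comp[1:n, ((k - 1) * n + 1):(k * n)] <- coefficients[[k]]
  }
  if (p > 1) {
    comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an sVAR fit into a long coefficient table
#'
#' @param x An `svar_fit`.
#' @param all Include zero coefficients (default FALSE).
#' @param ... Unused.
#' @return A tibble with columns `target`, `source`, `lag`, `estimate`.
#' @exportS3Method generics::tidy
tidy.svar_fit <- function(x, all = FALSE, ...) {
  out <- purrr::map_dfr(seq_len(x$p), function(k) {
    m <- x$coefficients[[k]]
    tibble::tibble(target = rep(rownames(m), times = ncol(m)),
                   source = rep(colnames(m), each = nrow(m)),
                   lag = k, estimate = as.vector(m))
  })
  if (!all) out <- dplyr::filter(out, .data$estimate != 0)
  out
}

#' @exportS3Method generics::glance
glance.svar_fit <- function(x, ...) {
  nz <- tidy(x)
  tibble::tibble(
    p = x$p, n_taxa = length(x$taxon_ids), n_obs = nrow(x$residuals),
    n_nonzero = nrow(nz),
    n_cross = sum(nz$source != nz$target),
    median_r_squared = stats::median(x$r_squared, na.rm = TRUE),
    max_r_squared = max(x$r_squared, na.rm = TRUE),
    spectral_radius = companion_spectral_radius(x$coefficients)
  )
}
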