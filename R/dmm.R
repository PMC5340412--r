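# Dirichlet-multinomial mixtures: EM fitting, Laplace model selection,
# and the temporal-subsampling state-decay analysis.

# log DM pmf for every row of a count matrix X (samples x taxa) under one
# component with parameter vector alpha; includes the multinomial
# coefficient so values are comparable across K.
dm_logpmf <- function(X, alpha) {
  N <- rowSums(X)
  A <- sum(alpha)
  base <- lgamma(N + 1) - rowSums(lgamma(X + 1)) + lgamma(A) - lgamma(A + N)
  base + rowSums(lgamma(sweep(X, 2, alpha, "+"))) - sum(lgamma(alpha))
}

# weighted Minka fixed-point update of one component's alpha vector
update_alpha <- function(X, w, alpha, n_inner = 10, floor = 1e-6) {
  N <- rowSums(X)
  sw <- sum(w)
  if (sw < 1e-12) return(alpha)
  for (it in seq_len(n_inner)) {
    A <- sum(alpha)
    denom <- sum(w * (digamma(N + A) - digamma(A)))
    if (denom <= 0) break
    num <- colSums(w * (digamma(sweep(X, 2, alpha, "+")) -
                          matrix(digamma(alpha), nrow(X), ncol(X), byrow = TRUE)))
    new <- alpha * pmax(num, 0) / denom
    new <- pmax(new, floor)
    if (max(abs(new - alpha) / (alpha + 1e-8)) < 1e-8) { alpha <- new; break }
    alpha <- new
  }
  alpha
}

# method-of-moments alpha for a weighted set of samples; EM initializer
alpha_moments <- function(X, w, floor = 1e-6) {
  N <- rowSums(X)
  P <- X / N
  sw <- sum(w)
  pbar <- colSums(w * P) / sw
  v <- colSums(w * sweep(P, 2, pbar)^2) / max(sw - 1, 1)
  use <- pbar > 0 & v > 0
  s <- stats::median(pbar[use] * (1 - pbar[use]) / v[use] - 1)
  if (!is.finite(s) || s <= 0) s <- 10
  pmax(pbar * s, floor)
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Community "states" are the mixture components: each sample's counts are
#' modelled as multinomial draws whose underlying composition comes from one
#' of `K` Dirichlet distributions. The E-step computes component
#' responsibilities from the Dirichlet-multinomial log-pmf; the M-step
#' updates weights from responsibilities and each alpha vector by a bounded
#' fixed-point iteration. Initialization is k-means on proportion vectors;
#' the best of `restarts` runs (by final log-likelihood) is kept.
#'
#' The reported `laplace_score` is the negative log model evidence under a
#' diagonal Laplace approximation at the fitted parameters:
#' `-logL + 0.5 * sum(log h) - (d/2) * log(2*pi)`, where the curvatures `h`
#' are (i) for each alpha entry, the observed information in log-alpha
#' coordinates, `alpha^2 * |d2 logL / d alpha^2|`, with the second
#' derivative accumulated through the responsibilities (trigamma terms),
#' and (ii) for each of the `K - 1` free mixture weights, `m / pi_k`, the
#' multinomial information in the component counts. `d = K*n + K - 1`.
#' Smaller scores indicate better penalized fits.
#'
#' @param counts An `otu_table` with count units and at least `K` samples.
#' @param K Number of components (>= 1).
#' @param seed Integer seed (controls k-means initialization).
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Relative log-likelihood convergence threshold (default 1e-6).
#' @param restarts Number of random restarts (default 3).
#' @return An object of class `dmm_fit`: `K`, `weights`, `alphas`
#'   (taxa x K matrix), `assignments` (MAP component per sample),
#'   `responsibilities`, `log_likelihood`, `ll_trace`, `laplace_score`,
#'   `converged`.
#' @export
fit_dmm <- function(counts, K, seed = 1, max_iter = 200, tol = 1e-6,
                    restarts = 3) {
  stopifnot(inherits(counts, "otu_table"))
  if (counts$units != "counts") stop("fit_dmm() needs a count table")
  if (any(counts$values != round(counts$values))) stop("counts must be integers")
  if (K < 1 || K != round(K)) stop("`K` must be a positive integer")
  X <- t(counts$values)
  m <- nrow(X)
  if (K > m) stop("K exceeds the number of samples")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed * 1000L + r, dmm_em_once(X, K, max_iter, tol))
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
    if (K == 1) break
  }
  best$laplace_score <- dmm_laplace_score(X, best)
  best$sample_ids <- counts$sample_ids
  best$sample_days <- counts$sample_days
  best$taxon_ids <- counts$taxon_ids
  dimnames(best$alphas) <- list(counts$taxon_ids, NULL)
  class(best) <- "dmm_fit"
  best
}

dmm_em_once <- function(X, K, max_iter, tol) {
  m <- nrow(X); n <- ncol(X)
  P <- X / rowSums(X)
  if (K == 1) {
    assign0 <- rep(1L, m)
  } else {
    km <- tryCatch(stats::kmeans(P, centers = K, nstart = 3),
                   error = function(e) NULL)
    assign0 <- if (is.null(km)) sample(rep_len(seq_len(K), m)) else km$cluster
  }
  R <- matrix(0, m, K)
  R[cbind(seq_len(m), assign0)] <- 1
  pi_k <- pmax(colMeans(R), 1e-8); pi_k <- pi_k / sum(pi_k)
  alphas <- vapply(seq_len(K), function(k) alpha_moments(X, R[, k]),
                   numeric(n))
  alphas <- matrix(alphas, n, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(K), function(k) dm_logpmf(X, alphas[, k]),
                   numeric(m))
    logp <- matrix(logp, m, K)
    lw <- sweep(logp, 2, log(pi_k), "+")
    mx <- apply(lw, 1, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    ll_trace <- c(ll_trace, ll)
    R <- exp(lw - mx)
    R <- R / rowSums(R)
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll_old) + 1) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi_k <- pmax(colMeans(R), 1e-8); pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      alphas[, k] <- update_alpha(X, R[, k], alphas[, k])
    }
  }
  list(K = K, weights = pi_k, alphas = alphas,
       assignments = max.col(R), responsibilities = R,
       log_likelihood = ll_trace[[length(ll_trace)]],
       ll_trace = ll_trace, converged = converged)
}

# Negative log model evidence by a diagonal Laplace approximation with a
# weak lognormal prior on each alpha (log alpha ~ N(0, sigma^2), sigma = 10).
# Writing h for the observed information of one parameter in log-alpha
# coordinates (h = alpha^2 * |d2 logL / d alpha^2|, second derivative
# accumulated through the responsibilities), the per-parameter evidence
# contribution of the prior-times-Laplace integral is
#   -1/2 log(1 + sigma^2 h) - (log alpha)^2 / (2 sigma^2):
# an informative parameter pays ~ -1/2 log(sigma^2 h) (BIC-like), while a
# flat direction (h -> 0, e.g. a background taxon never observed in a
# component) integrates to its prior mass and pays nothing. Without the
# prior the approximation diverges along flat directions and rewards
# complexity. Mixture weights contribute their multinomial information
# m / pi_k for the K - 1 free weights.
dmm_laplace_score <- function(X, fit, prior_sd = 10) {
  m <- nrow(X); K <- fit$K
  N <- rowSums(X)
  s2 <- prior_sd^2
  penalty <- 0
  for (k in seq_len(K)) {
    a <- fit$alphas[, k]
    r <- fit$responsibilities[, k]
    A <- sum(a)
    common <- sum(r * (trigamma(A) - trigamma(A + N)))
    d2 <- common + colSums(r * trigamma(sweep(X, 2, a, "+"))) -
      sum(r) * trigamma(a)
    h <- pmax(a^2 * abs(d2), 0)
    penalty <- penalty + sum(0.5 * log1p(s2 * h) + log(a)^2 / (2 * s2))
  }
  if (K > 1) {
    penalty <- penalty + 0.5 * sum(log1p(m / fit$weights[seq_len(K - 1)]))
  }
  -fit$log_likelihood + penalty
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf("<dmm_fit> K = %d, logL = %.2f, Laplace = %.2f, %s\n",
              x$K, x$log_likelihood, x$laplace_score,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dmm_fit <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids, day = x$sample_days,
                 state = x$assignments)
}

#' @exportS3Method generics::glance
glance.dmm_fit <- function(x, ...) {
  tibble::tibble(K = x$K, log_likelihood = x$log_likelihood,
                 laplace_score = x$laplace_score, converged = x$converged)
}

#' Select the number of community states by Laplace score
#'
#' Fits mixtures with `K = 1..k_max` (each with random restarts) and
#' returns the `K` minimizing the Laplace approximation to the negative
#' log model evidence.
#'
#' @param counts An `otu_table` with count units.
#' @param k_max Largest component count to try.
#' @param seed Integer seed.
#' @param restarts Restarts per K (default 3).
#' @param ... Passed to [fit_dmm()].
#' @return An object of class `dmm_selection`: list with `best_k`,
#'   `scores` (tibble K / log_likelihood / laplace_score), `best_fit`.
#' @export
select_k <- function(counts, k_max, seed = 1, restarts = 3, ...) {
  if (k_max < 1) stop("`k_max` must be >= 1")
  k_max <- min(k_max, n_samples(counts))
  fits <- lapply(seq_len(k_max), function(k) {
    fit_dmm(counts, k, seed = seed + 17L * k, restarts = restarts, ...)
  })
  scores <- purrr::map_dfr(fits, glance)
  best <- which.min(scores$laplace_score)
  structure(list(best_k = best, scores = scores, best_fit = fits[[best]]),
            class = "dmm_selection")
}

#' @export
print.dmm_selection <- function(x, ...) {
  cat(sprintf("<dmm_selection> best K = %d of %d tried\n",
              x$best_k, nrow(x$scores)))
  invisible(x)
}

#' State decay under temporal subsampling
#'
#' Pools the samples of one or more subjects' time series and refits the
#' state model at increasing temporal stride: every time point, every
#' other, every third, and so on. For each stride, every phase offset is
#' evaluated and the modal selected `K` across phases is reported (ties go
#' to the smaller `K`). Genuinely discrete states show a plateau in `K`
#' across strides; pseudo-clusters from dense sampling of a continuous
#' trajectory decay toward 1. Per-stride state-to-subject assignment
#' counts (from the first phase) expose whether states are shared across
#' subjects or subject-pure.
#'
#' @param tables Named list of `otu_table`s (count units, same taxa, each
#'   time-ordered).
#' @param max_stride Largest stride to evaluate.
#' @param k_max Largest component count per selection.
#' @param seed Integer seed.
#' @param restarts Restarts per K (default 2; decay scans are expensive).
#' @return An object of class `state_decay`: `curve` (tibble stride /
#'   best_k), `assignments` (tibble stride / subject / sample_id / day /
#'   state, first phase), `sharing` (tibble stride / state / subject /
#'   n_samples).
#' @export
state_decay <- function(tables, max_stride, k_max, seed = 1, restarts = 2) {
  if (!is.list(tables) || length(tables) < 1) stop("need at least one table")
  if (inherits(tables, "otu_table")) tables <- list(subject1 = tables)
  if (is.null(names(tables))) names(tables) <- paste0("subject", seq_along(tables))
  ids <- lapply(tables, function(t) t$taxon_ids)
  if (length(unique(lapply(ids, sort))) != 1) {
    stop("all tables must share one taxon set")
  }
  ref <- ids[[1]]
  curve <- list(); assigns <- list(); sharing <- list()
  for (s in seq_len(max_stride)) {
    ks <- integer(0)
    first_fit <- NULL; first_meta <- NULL
    for (phase in seq_len(s)) {
      sub <- purrr::map(names(tables), function(nm) {
        t <- tables[[nm]]
        idx <- seq(phase, n_samples(t), by = s)
        list(values = t$values[match(ref, t$taxon_ids), idx, drop = FALSE],
             days = t$sample_days[idx],
             ids = paste0(nm, ":", t$sample_ids[idx]),
             subject = rep(nm, length(idx)))
      })
      pooled_vals <- do.call(cbind, purrr::map(sub, "values"))
      subj <- unlist(purrr::map(sub, "subject"))
      if (ncol(pooled_vals) < k_max) next
      pooled <- otu_table(pooled_vals, ref,
                          sample_days = seq_len(ncol(pooled_vals)),
                          sample_ids = unlist(purrr::map(sub, "ids")),
                          units = "counts")
      selk <- select_k(pooled, k_max, seed = seed + 101L * s + phase,
                       restarts = restarts)
      ks <- c(ks, selk$best_k)
      if (phase == 1) {
        first_fit <- selk$best_fit
        first_meta <- list(subject = subj,
                           day = unlist(purrr::map(sub, "days")))
      }
    }
    if (length(ks) == 0) {
      warning(sprintf("stride %d leaves fewer than k_max samples; skipped", s))
      next
    }
    tab_k <- table(ks)
    best_k <- as.integer(names(tab_k)[which.max(tab_k)])
    curve[[length(curve) + 1]] <- tibble::tibble(stride = s, best_k = best_k)
    if (!is.null(first_fit)) {
      a <- tibble::tibble(stride = s, subject = first_meta$subject,
                          sample_id = first_fit$sample_ids,
                          day = first_meta$day,
                          state = first_fit$assignments)
      assigns[[length(assigns) + 1]] <- a
      sharing[[length(sharing) + 1]] <- dplyr::count(
        a, .data$stride, .data$state, .data$subject, name = "n_samples")
    }
  }
  structure(list(curve = dplyr::bind_rows(curve),
                 assignments = dplyr::bind_rows(assigns),
                 sharing = dplyr::bind_rows(sharing)),
            class = "state_decay")
}

#' @export
print.state_decay <- function(x, ...) {
  cat("<state_decay>\n")
  print(x$curve, n = Inf)
  invisible(x)
}
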