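#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (elpd) under
#' leave-one-out cross-validation from a pointwise log-likelihood matrix:
#' per-trial importance ratios `1 / p(y_i | theta_s)` are stabilised by
#' replacing their largest values with expected order statistics of a
#' generalized Pareto distribution fitted to the upper tail (Pareto
#' smoothing), then self-normalised.  The tail-shape diagnostic
#' \eqn{\hat{k}} is reported per trial.
#'
#' @param x A `ddm_fit` (its `pointwise_loglik` is used) or a numeric
#'   matrix of pointwise log likelihoods (draws x observations).
#' @return Object of class `loo_result`: `elpd_loo`, `se`, `pointwise`,
#'   `pareto_k`, `n_draws`.
#' @export
psis_loo <- function(x) {
  ll <- if (inherits(x, "ddm_fit")) x$pointwise_loglik else as.matrix(x)
  S <- nrow(ll); n <- ncol(ll)
  if (S < 100) stop("psis_loo needs at least 100 draws")
  pointwise <- numeric(n); khat <- numeric(n)
  degenerate <- TRUE
  for (i in seq_len(n)) {
    lr <- -ll[, i]
    if (diff(range(lr)) > 1e-10) degenerate <- FALSE
    sm <- .psis_smooth(lr - max(lr))
    lw <- sm$lw
    khat[i] <- sm$khat
    # elpd_i = log( sum w_s p(y_i|theta_s) / sum w_s )
    pointwise[i] <- .logsumexp(lw + ll[, i]) - .logsumexp(lw)
  }
  if (degenerate) {
    warning("all posterior draws identical; returning exact pointwise ",
            "log-likelihood (importance weights collapse)")
    pointwise <- ll[1, ]
    khat <- rep(0, n)
  }
  structure(list(elpd_loo = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = khat, n_draws = S),
            class = "loo_result")
}

.logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Pareto-smooth a vector of (shifted) log weights; returns smoothed log
# weights and the tail-shape estimate
.psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || diff(range(lw)) < 1e-10)
    return(list(lw = lw, khat = -Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exceed <= 0)) return(list(lw = lw, khat = -Inf))
  fit <- .gpd_fit(sort(exceed))
  if (!is.finite(fit$k)) return(list(lw = lw, khat = fit$k))
  p <- (seq_len(M) - 0.5) / M
  qq <- .qgpd(p, fit$k, fit$sigma) + exp(cutoff)
  smoothed <- pmin(log(qq), max(lw))          # cap at largest raw weight
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  list(lw = lw, khat = fit$k)
}

# Zhang & Stephens (2009) style profile-posterior fit of the generalized
# Pareto distribution to sorted exceedances; returns shape k (xi) and scale
.gpd_fit <- function(x, prior_bs = 3, prior_k = 10) {
  N <- length(x)
  if (N < 5 || x[N] <= 0) return(list(k = Inf, sigma = NA_real_))
  x <- pmax(x, 1e-300)
  M <- 30 + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(floor(N / 4 + 0.5), 1)]
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (prior_bs * xstar)
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_theta <- N * (log(-theta / k_j) - k_j - 1)
  ok <- is.finite(l_theta)
  if (!any(ok)) return(list(k = Inf, sigma = NA_real_))
  theta <- theta[ok]; l_theta <- l_theta[ok]; k_j <- k_j[ok]
  w <- exp(l_theta - .logsumexp(l_theta))
  theta_hat <- sum(theta * w)
  k_hat <- mean(log1p(-theta_hat * x))
  sigma <- -k_hat / theta_hat
  # weakly informative regularisation of the shape towards 0.5
  k_hat <- (N * k_hat + prior_k * 0.5) / (N + prior_k)
  list(k = k_hat, sigma = sigma)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' @export
print.loo_result <- function(x, ...) {
  cat("PSIS-LOO: elpd_loo =", round(x$elpd_loo, 2),
      "(se", paste0(round(x$se, 2), ")"),
      "| max Pareto k =", round(max(x$pareto_k), 3), "\n")
  invisible(x)
}

#' Unsmoothed importance-sampling LOO
#'
#' Plain self-normalised importance-sampling estimate of the pointwise
#' leave-one-out elpd (no Pareto smoothing, no truncation).  Intended for
#' tiny, well-behaved problems as a cross-check on [psis_loo()].
#'
#' @param ll Pointwise log-likelihood matrix (draws x observations).
#' @return Vector of pointwise elpd values.
#' @export
exact_loo_pointwise <- function(ll) {
  vapply(seq_len(ncol(ll)), function(i) {
    lw <- -ll[, i]
    .logsumexp(lw + ll[, i]) - .logsumexp(lw)
  }, numeric(1))
}
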