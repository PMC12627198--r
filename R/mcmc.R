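# Generic posterior sampler used for all models in the package.
#
# Strategy: locate the posterior mode (Nelder-Mead then BFGS) and take the
# Laplace covariance from the numerical Hessian.  Each chain then runs a
# short adaptive random-walk warmup to refine the posterior covariance and
# switches to a rotated componentwise slice sampler (Neal 2003): one sweep
# updates the state along each principal axis of the estimated covariance
# with stepping-out and shrinkage.  Slice sampling is rejection-free and
# self-tuning, which keeps autocorrelation low enough for tight
# split-Rhat thresholds at moderate chain lengths.

.chol_safe <- function(S) {
  d <- nrow(S)
  for (ridge in c(0, 1e-8, 1e-6, 1e-4, 1e-2)) {
    R <- tryCatch(chol(S + diag(ridge, d)), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  chol(diag(pmax(diag(S), 1e-4), d))
}

.find_map <- function(logpost, d, n_restarts = 2L) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) rep(0, d) else rnorm(d, 0, 0.5)
    if (!is.finite(logpost(init))) init <- rep(0, d)
    o1 <- optim(init, function(th) -logpost(th), method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
    o2 <- tryCatch(
      optim(o1$par, function(th) -logpost(th), method = "BFGS",
            control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  H <- tryCatch(optimHess(best$par, function(th) -logpost(th)),
                error = function(e) diag(1, d))
  S <- tryCatch(solve(H), error = function(e) diag(0.1, d))
  if (any(!is.finite(S)) || any(diag(S) <= 0)) S <- diag(0.1, d)
  list(par = best$par, value = -best$value, cov = (S + t(S)) / 2)
}

# one slice-sampling update along direction `dir` from state (theta, lp);
# stepping-out with doubling cap, then shrinkage (Neal 2003)
.slice_move <- function(logpost, theta, lp, dir, width, max_steps = 30L) {
  y <- lp - stats::rexp(1)
  L <- -width * runif(1); R <- L + width
  k <- max_steps
  while (k > 0 && is.finite(lpL <- logpost(theta + L * dir)) && lpL > y) {
    L <- L - width; k <- k - 1L
  }
  k <- max_steps
  while (k > 0 && is.finite(lpR <- logpost(theta + R * dir)) && lpR > y) {
    R <- R + width; k <- k - 1L
  }
  repeat {
    x <- runif(1, L, R)
    lpx <- logpost(theta + x * dir)
    if (is.finite(lpx) && lpx > y)
      return(list(theta = theta + x * dir, lp = lpx))
    if (x < 0) L <- x else R <- x
    if (R - L < 1e-12) return(list(theta = theta, lp = lp))
  }
}

.run_chain <- function(logpost, map, n_warmup, n_sampling, d) {
  cL0 <- .chol_safe(map$cov)
  theta <- map$par + 0.3 * drop(crossprod(cL0, rnorm(d)))
  lp <- logpost(theta)
  if (!is.finite(lp)) { theta <- map$par; lp <- logpost(theta) }
  n1 <- max(min(floor(n_warmup / 2), 300L), 20L)
  ls <- log(2.38 / sqrt(d))
  warm1 <- matrix(NA_real_, n1, d)
  n_acc <- 0L
  for (i in seq_len(n1)) {                       # adaptive random walk
    prop <- theta + exp(ls) * drop(crossprod(cL0, rnorm(d)))
    lpp <- logpost(prop)
    acc <- is.finite(lpp) && log(runif(1)) < lpp - lp
    if (acc) { theta <- prop; lp <- lpp; n_acc <- n_acc + 1L }
    ls <- ls + (as.numeric(acc) - 0.234) / i^0.6
    warm1[i, ] <- theta
  }
  Semp <- stats::cov(warm1)
  if (any(!is.finite(Semp))) Semp <- map$cov
  S1 <- 0.5 * map$cov + 0.5 * Semp + diag(1e-10, d)
  axes <- function(S) {
    eg <- eigen(S, symmetric = TRUE)
    list(dirs = eg$vectors, widths = 2.5 * sqrt(pmax(eg$values, 1e-12)))
  }
  ax <- axes(S1)
  n2 <- n_warmup - n1
  # remaining warmup: slice sweeps, with the principal axes re-estimated
  # midway from the (much better mixed) slice draws themselves
  n2a <- floor(n2 / 2)
  warm2 <- matrix(NA_real_, n2a, d)
  state <- list(theta = theta, lp = lp)
  for (i in seq_len(n2a)) {
    for (j in sample.int(d))
      state <- .slice_move(logpost, state$theta, state$lp,
                           ax$dirs[, j], ax$widths[j])
    warm2[i, ] <- state$theta
  }
  if (n2a >= 5 * d) {
    S2 <- stats::cov(warm2)
    if (all(is.finite(S2))) ax <- axes(0.2 * S1 + 0.8 * S2 + diag(1e-10, d))
  }
  draws <- matrix(NA_real_, n_sampling, d)
  lps <- numeric(n_sampling)
  for (i in seq_len((n2 - n2a) + n_sampling)) {
    for (j in sample.int(d))
      state <- .slice_move(logpost, state$theta, state$lp,
                           ax$dirs[, j], ax$widths[j])
    if (i > n2 - n2a) {
      draws[i - (n2 - n2a), ] <- state$theta
      lps[i - (n2 - n2a)] <- state$lp
    }
  }
  list(draws = draws, lp = lps, accept = max(n_acc / n1, 1))
}

#' Sample a posterior with the package's Metropolis engine
#'
#' @param logpost Function of the unconstrained parameter vector returning
#'   the log posterior density (up to a constant).
#' @param d Parameter dimension.
#' @param n_chains,n_warmup,n_sampling Chain configuration.
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @return List with `chains` (list of `n_sampling` x `d` matrices),
#'   `map` (mode, log posterior, Laplace covariance) and `accept` rates.
#' @export
mcmc_sample <- function(logpost, d, n_chains = 2, n_warmup = 1000,
                        n_sampling = 1000, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  map <- .find_map(logpost, d)
  chains <- vector("list", n_chains)
  accept <- numeric(n_chains)
  for (cc in seq_len(n_chains)) {
    set.seed((as.integer(seed) + cc) %% .Machine$integer.max)
    res <- .run_chain(logpost, map, n_warmup, n_sampling, d)
    chains[[cc]] <- res$draws
    accept[cc] <- res$accept
  }
  list(chains = chains, map = map, accept = accept)
}

#' Split-\eqn{\hat{R}} convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction computed on split chains (each
#' chain halved, between/within variance ratio).
#'
#' @param chains List of draw matrices (iterations x parameters), one per
#'   chain; at least 2 chains.
#' @return Named vector of split-\eqn{\hat{R}} values, one per parameter.
#' @export
split_rhat <- function(chains) {
  if (length(chains) < 2L)
    stop("split_rhat needs at least 2 chains")
  d <- ncol(chains[[1]])
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch); h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  out <- numeric(d)
  for (j in seq_len(d)) {
    x <- vapply(halves, function(h) h[, j], numeric(n))
    mns <- colMeans(x); vrs <- apply(x, 2, stats::var)
    W <- mean(vrs); B <- n * stats::var(mns)
    if (W <= 0) { out[j] <- if (B <= 0) 1 else Inf; next }
    var_plus <- (n - 1) / n * W + B / n
    out[j] <- sqrt(var_plus / W)
  }
  nms <- colnames(chains[[1]])
  if (!is.null(nms)) names(out) <- nms
  out
}
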