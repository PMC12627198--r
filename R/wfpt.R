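#' Wiener first-passage-time log density
#'
#' Log density of the first passage of a unit-variance Wiener process with
#' drift `v`, absorbing boundaries at 0 and `A`, and starting point `z * A`,
#' at observed time `t` (seconds, including the non-decision time `t0`).
#' Times at or below `t0` are impossible observations and return `-Inf`.
#' The series is truncated so the absolute density error is below `eps`
#' (short-time vs long-time expansion chosen per evaluation).
#'
#' @param t Observed response time(s), seconds.
#' @param boundary `"upper"` (variable option) or `"lower"` (constant
#'   option); recycled.
#' @param A Boundary separation (> 0).
#' @param t0 Non-decision time (>= 0), seconds.
#' @param z Relative starting point in (0, 1).
#' @param v Drift rate(s); scalar or one per element of `t`.
#' @param eps Series truncation tolerance on the density.
#' @return Vector of log densities.
#' @export
wfpt_logpdf <- function(t, boundary, A, t0, z, v, eps = 1e-9) {
  stopifnot(A > 0, t0 >= 0, z > 0, z < 1)
  boundary <- match.arg(boundary, c("upper", "lower"), several.ok = TRUE)
  up <- rep_len(boundary == "upper", length(t))
  .wfpt_lpdf_cpp(as.numeric(t), up, A, t0, z, as.numeric(v), eps)
}

#' Probability of choosing the variable option
#'
#' Absorption probability at the upper boundary,
#' `P = (exp(-2*A*z*v) - 1) / (exp(-2*A*v) - 1)`,
#' evaluated stably with the continuous limit `P -> z` as `v -> 0`.
#'
#' @inheritParams wfpt_logpdf
#' @return Probability (vector if `v` is a vector).
#' @export
choice_prob_upper <- function(A, z, v) {
  stopifnot(A > 0, z > 0, z < 1)
  .prob_upper_cpp(A, z, as.numeric(v))
}

#' Per-trial log likelihood
#'
#' Single-response trials contribute the full WFPT density of (RT, choice);
#' preference-switch trials indicate multiple accumulation episodes, so only
#' the choice is modelled, via the absorption probability.  The upper
#' boundary always maps to the variable (later-larger / risky) option.
#' Records flagged as RT outliers are excluded observations and refuse a
#' likelihood.
#'
#' @param records Data frame with columns `rt`, `choice`
#'   (`"variable"`/`"constant"`), `n_switches`, optionally `is_rt_outlier`.
#' @param model Registry entry or model id.
#' @param params Named natural-scale parameter values including `A`, `t0`,
#'   `z` and the model's drift parameters.
#' @param strict_printed See [drift_rate()].
#' @return Vector of pointwise log likelihoods (one per record).
#' @export
trial_loglik <- function(records, model, params, strict_printed = FALSE) {
  if (is.character(model)) model <- ddm_model(model)
  if (!is.null(records$is_rt_outlier) && any(records$is_rt_outlier))
    stop("records contain RT-outlier trials; exclude them before computing ",
         "the likelihood")
  p <- as.list(params)
  v <- drift_rate(model, p, records, strict_printed)
  .ddm_pointwise_cpp(as.numeric(records$rt),
                     records$choice == "variable",
                     records$n_switches >= 1L,
                     p$A, p$t0, p$z, v)
}

#' Simulate first-passage outcomes
#'
#' `rwfpt()` draws (boundary, decision time) pairs from the WFPT process by
#' sampling the boundary from the exact absorption probability and the
#' decision time by numerical inversion of the conditional first-passage
#' CDF (series density integrated on an adaptive grid).
#' `rwfpt_euler()` is a forward Euler-Maruyama simulator used as an
#' independent oracle.
#'
#' @param n Number of draws.
#' @inheritParams wfpt_logpdf
#' @param dt Euler step (seconds).
#' @param tmax Censoring time for the Euler simulator.
#' @return Data frame with columns `upper` (logical) and `dt`
#'   (decision time, seconds; add `t0` for an RT).
#' @export
rwfpt <- function(n, A, z, v) {
  stopifnot(A > 0, z > 0, z < 1)
  p_up <- choice_prob_upper(A, z, v)
  up <- runif(n) < p_up
  out <- numeric(n)
  for (b in c(TRUE, FALSE)) {
    idx <- which(up == b)
    if (!length(idx)) next
    qf <- .wfpt_cond_quantile_fun(A, z, v, upper = b)
    out[idx] <- qf(runif(length(idx)))
  }
  data.frame(upper = up, dt = out)
}

# conditional quantile function of the decision time given the boundary,
# via trapezoid CDF of the series density on a time grid refined until the
# conditional mass is captured
.wfpt_cond_quantile_fun <- function(A, z, v, upper, ngrid = 800L) {
  p_b <- choice_prob_upper(A, z, v)
  if (!upper) p_b <- 1 - p_b
  if (p_b < 1e-12) return(function(u) rep(A^2, length(u)))  # unreachable arm
  # time scale shrinks under strong drift (mean passage ~ distance/|v|)
  tmax <- 2 * A^2 / (1 + abs(v) * A / 2)
  repeat {
    grid <- seq(0, tmax, length.out = ngrid)[-1]
    d <- exp(.wfpt_lpdf_cpp(grid, rep(upper, length(grid)), A, 0, z,
                            rep(as.numeric(v), length(grid))))
    cdf <- cumsum((d[-1] + d[-length(d)]) / 2 * diff(grid))
    cdf <- c(0, cdf)
    if (cdf[length(cdf)] >= p_b * (1 - 1e-7) || tmax > 1e4) break
    tmax <- tmax * 2
    ngrid <- min(ngrid * 2L, 6400L)
  }
  cdf <- cdf / cdf[length(cdf)]
  # strictly increasing knots for interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  ca <- cdf[keep]; ta <- grid[keep]
  if (length(ta) < 2L) return(function(u) rep(ta[1], length(u)))
  function(u) stats::approx(ca, ta, xout = u, rule = 2)$y
}

#' @rdname rwfpt
#' @export
rwfpt_euler <- function(n, A, z, v, dt = 1e-3, tmax = 60) {
  res <- .sim_ddm_euler_cpp(as.integer(n), v, A, z, dt, tmax)
  data.frame(upper = res$upper == 1L, dt = res$dt)
}

#' Closed-form mean decision time at an unbiased start
#'
#' For `z = 0.5` the mean first-passage time is
#' `(A / (2 v)) * tanh(A * v / 2)` (limit `A^2 / 4` at `v = 0`).
#' @inheritParams wfpt_logpdf
#' @export
mean_decision_time <- function(A, v) {
  ifelse(abs(v) < 1e-9, A^2 / 4, (A / (2 * v)) * tanh(A * v / 2))
}
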