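#' MCMC configuration
#'
#' Defaults reproduce the reference fitting setup: two chains, 4,500
#' sampling iterations after 3,500 warm-up iterations, convergence declared
#' at split-\eqn{\hat{R}} < 1.005 for every parameter.  Scaled-down
#' configurations (e.g. `mcmc_config(n_warmup = 500, n_sampling = 500)`)
#' are used for recovery studies and tests.
#'
#' @param n_chains,n_warmup,n_sampling Chain sizes.
#' @param seed Integer seed.
#' @param rhat_threshold Convergence threshold on split-\eqn{\hat{R}}.
#' @param min_trials Minimum usable trials required to fit a participant.
#' @param prior_sd Prior standard deviation on the unconstrained scale.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_warmup = 3500, n_sampling = 4500,
                        seed = 1, rhat_threshold = 1.005, min_trials = 50,
                        prior_sd = 5) {
  structure(list(n_chains = n_chains, n_warmup = n_warmup,
                 n_sampling = n_sampling, seed = seed,
                 rhat_threshold = rhat_threshold, min_trials = min_trials,
                 prior_sd = prior_sd),
            class = "mcmc_config")
}

# unconstrained theta -> natural-scale named parameter list
theta_to_params <- function(model, theta) {
  out <- list()
  for (i in seq_along(model$param_meta)) {
    m <- model$param_meta[[i]]
    out[[m$name]] <- switch(m$transform,
      log = m$scale * exp(theta[i]),
      logit = plogis(theta[i]),
      identity = theta[i])
  }
  out
}

params_to_theta <- function(model, params) {
  vapply(model$param_meta, function(m) {
    x <- params[[m$name]]
    switch(m$transform,
           log = log(x / m$scale),
           logit = qlogis(x),
           identity = x)
  }, numeric(1))
}

.ddm_logpost_factory <- function(records, model, prior_sd) {
  rt <- as.numeric(records$rt)
  up <- records$choice == "variable"
  sw <- records$n_switches >= 1L
  # plain list of columns: far cheaper `$` access than a data.frame in the
  # inner sampling loop
  tr <- as.list(records[, intersect(c("amount", "delay_days", "prob_win",
                                      "amb_days", "amb_prob"),
                                    names(records))])
  function(theta) {
    p <- theta_to_params(model, theta)
    v <- model$drift_fun(p, tr, FALSE)
    if (any(!is.finite(v))) return(-Inf)
    ll <- sum(.ddm_pointwise_cpp(rt, up, sw, p$A, p$t0, p$z, v))
    if (!is.finite(ll)) return(-Inf)
    ll + sum(dnorm(theta, 0, prior_sd, log = TRUE))
  }
}

#' Fit one participant's data with a drift-rate model
#'
#' Per-participant Bayesian estimation: wide normal priors on the
#' unconstrained scale (positivity via log, starting point via logit),
#' posterior explored with the package's Metropolis engine
#' ([mcmc_sample()]).  Catch trials and RT-outlier trials are removed
#' before the likelihood is formed; the pointwise log-likelihood matrix
#' covers every retained trial.
#'
#' @param records One participant's behavioural records.
#' @param model Registry entry or model id.
#' @param cfg An [mcmc_config()].
#' @param participant Optional participant id stored in the fit.
#' @return Object of class `ddm_fit`: `draws` (per chain, natural scale),
#'   `draws_theta`, `pointwise_loglik` (total draws x trials), `rhat`,
#'   `map`, `accept`, `model_id`, `usable`.
#' @export
fit_participant <- function(records, model, cfg = mcmc_config(),
                            participant = NA) {
  if (is.character(model)) model <- ddm_model(model)
  records <- records[records$kind != "catch", , drop = FALSE]
  records <- flag_outlier_trials(records)
  records <- records[!records$is_rt_outlier, , drop = FALSE]
  if (nrow(records) < cfg$min_trials)
    stop("fewer than ", cfg$min_trials, " usable trials")
  lpfun <- .ddm_logpost_factory(records, model, cfg$prior_sd)
  d <- length(model$param_names)
  res <- mcmc_sample(lpfun, d, cfg$n_chains, cfg$n_warmup, cfg$n_sampling,
                     cfg$seed)
  for (i in seq_along(res$chains))
    colnames(res$chains[[i]]) <- model$param_names
  rhat <- split_rhat(res$chains)
  theta_all <- do.call(rbind, res$chains)
  nat <- t(apply(theta_all, 1, function(th)
    unlist(theta_to_params(model, th))))
  colnames(nat) <- model$param_names
  # pointwise log likelihood for every retained trial at every draw
  rt <- as.numeric(records$rt); up <- records$choice == "variable"
  sw <- records$n_switches >= 1L
  pll <- matrix(NA_real_, nrow(theta_all), nrow(records))
  for (s in seq_len(nrow(theta_all))) {
    p <- theta_to_params(model, theta_all[s, ])
    v <- model$drift_fun(p, records, FALSE)
    pll[s, ] <- .ddm_pointwise_cpp(rt, up, sw, p$A, p$t0, p$z, v)
  }
  usable <- all(is.finite(rhat)) && mean(res$accept) > 0.05
  structure(list(model_id = model$model_id, participant = participant,
                 draws = nat, draws_theta = res$chains,
                 pointwise_loglik = pll, rhat = rhat, map = res$map,
                 accept = res$accept, n_trials = nrow(records),
                 records = records, usable = usable, cfg = cfg),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("ddm_fit:", x$model_id, "| participant", x$participant, "\n")
  cat("  trials:", x$n_trials, " draws:", nrow(x$draws),
      " max split-Rhat:", round(max(x$rhat), 4), "\n")
  pm <- colMeans(x$draws)
  cat("  posterior means:\n")
  print(round(pm, 4))
  invisible(x)
}

#' Persist a fit to plain-text files
#'
#' Writes the posterior draws in long format (`chain`, `iteration`,
#' `name`, `value`), the pointwise log-likelihood matrix as CSV, and a
#' JSON metadata file (model, participant, configuration, diagnostics).
#'
#' @param fit A `ddm_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(fit$model_id, "_p", fit$participant))
  long <- do.call(rbind, lapply(seq_along(fit$draws_theta), function(cc) {
    ch <- fit$draws_theta[[cc]]
    nat <- t(apply(ch, 1, function(th)
      unlist(theta_to_params(ddm_model(fit$model_id), th))))
    data.frame(chain = cc, iteration = rep(seq_len(nrow(ch)), ncol(nat)),
               name = rep(colnames(nat), each = nrow(nat)),
               value = as.vector(nat))
  }))
  paths <- c(draws = paste0(stem, "_draws.csv"),
             loglik = paste0(stem, "_pointwise.csv"),
             meta = paste0(stem, "_meta.json"))
  write.csv(long, paths["draws"], row.names = FALSE)
  write.csv(fit$pointwise_loglik, paths["loglik"], row.names = FALSE)
  jsonlite::write_json(
    list(model_id = fit$model_id, participant = fit$participant,
         n_trials = fit$n_trials, rhat = as.list(fit$rhat),
         usable = fit$usable,
         cfg = fit$cfg[c("n_chains", "n_warmup", "n_sampling", "seed")]),
    paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Convergence check
#'
#' @param fit A `ddm_fit`.
#' @return List: `max_rhat`, `rhat` (per parameter), `pass`.
#' @export
check_convergence <- function(fit) {
  if (length(fit$draws_theta) < 2L)
    stop("convergence assessment requires at least 2 chains")
  rhat <- split_rhat(fit$draws_theta)
  names(rhat) <- colnames(fit$draws)
  list(max_rhat = max(rhat), rhat = rhat,
       pass = all(rhat < fit$cfg$rhat_threshold))
}

#' Parameter-recovery study
#'
#' Simulates participants from known parameters, refits the generating
#' model, and correlates true values with posterior means per parameter.
#'
#' @param model Registry entry or model id.
#' @param n_participants Number of simulated participants (>= 10).
#' @param cfg An [mcmc_config()] used for each fit.
#' @param pop A [population_spec()]; contaminant rates are typically set
#'   to zero for recovery studies.
#' @param seed Master seed for the simulated cohort.
#' @return List: `table` (data frame `param`, `r`, `n`), `truth`,
#'   `estimates`.
#' @export
recover_parameters <- function(model, n_participants = 20,
                               cfg = mcmc_config(n_warmup = 500,
                                                 n_sampling = 500),
                               pop = population_spec(p_rt_outlier = 0,
                                                     p_switch_trial = 0),
                               seed = 11) {
  if (is.character(model)) model <- ddm_model(model)
  if (n_participants < 10) stop("recovery needs >= 10 participants")
  dom <- model$domain
  mods <- setNames(model$model_id, dom)
  coh <- simulate_cohort(n_participants, seed = seed, models = mods,
                         pop = pop, domains = dom)
  est <- matrix(NA_real_, n_participants, length(model$param_names),
                dimnames = list(NULL, model$param_names))
  for (p in seq_len(n_participants)) {
    b <- coh$behavior[coh$behavior$participant == p, , drop = FALSE]
    cfg_p <- cfg; cfg_p$seed <- cfg$seed + p
    fit <- fit_participant(b, model, cfg_p, participant = p)
    est[p, ] <- colMeans(fit$draws)
  }
  truth <- coh$truth[order(coh$truth$participant),
                     model$param_names, drop = FALSE]
  tab <- do.call(rbind, lapply(model$param_names, function(nm) {
    tv <- truth[[nm]]
    r <- if (stats::sd(tv) == 0) NA_real_ else cor(tv, est[, nm])
    data.frame(param = nm, r = r, n = n_participants,
               degenerate = stats::sd(tv) == 0)
  }))
  list(table = tab, truth = truth, estimates = est)
}
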