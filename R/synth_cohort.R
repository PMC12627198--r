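#' Population specification for synthetic cohorts
#'
#' Describes the between-participant distribution of DDM parameters
#' (truncated normals on the natural scale), the fraction of
#' ambiguity-averse participants, contamination rates (RT outliers,
#' preference-switch trials) and the catch-trial error rate.  Ambiguity
#' parameters are sampled as a magnitude from their truncated normal and
#' signed so that the participant is ambiguity-averse with probability
#' `frac_ambiguity_averse`; across domains the aversion indicators share a
#' Gaussian copula with correlation `cross_domain_rho`, emulating a
#' partially shared ambiguity-attitude trait.
#'
#' Defaults: the averse fraction is 0.70; the RT-contamination rate 0.079
#' matches the average outlier-trial share observed in comparable online
#' cohorts; switch and catch-error rates are set to modest values typical
#' for attentive online samples (0.05 and 0.02).  Parameter locations and
#' scales are chosen so drifts over the printed trial grids span roughly
#' -3..3 evidence units/s and RTs fall mostly in 0.5-3 s.
#'
#' @param frac_ambiguity_averse Fraction of ambiguity-averse participants.
#' @param p_rt_outlier Per-trial probability of replacing the RT with a
#'   contaminant outside \[0.3 s, 10 s\].
#' @param p_switch_trial Per-trial probability of a preference-switch trial.
#' @param catch_error_rate Per-catch-trial probability of (erroneously)
#'   choosing the variable option.
#' @param cross_domain_rho Latent correlation of the aversion indicator
#'   across the delay and probability domains.
#' @param params Optional named list overriding individual parameter rows,
#'   each `c(location, scale, lower, upper)`.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(frac_ambiguity_averse = 0.70,
                            p_rt_outlier = 0.079,
                            p_switch_trial = 0.05,
                            catch_error_rate = 0.02,
                            cross_domain_rho = 0.3,
                            params = list()) {
  stopifnot(frac_ambiguity_averse >= 0, frac_ambiguity_averse <= 1,
            p_rt_outlier >= 0, p_rt_outlier < 1,
            p_switch_trial >= 0, p_switch_trial < 1)
  defaults <- .default_param_table()
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  bad <- vapply(defaults, function(r) r[2] < 0 || r[3] > r[4], TRUE)
  if (any(bad)) stop("unsatisfiable bounds/scales for: ",
                     paste(names(defaults)[bad], collapse = ", "))
  structure(list(params = defaults,
                 frac_ambiguity_averse = frac_ambiguity_averse,
                 p_rt_outlier = p_rt_outlier,
                 p_switch_trial = p_switch_trial,
                 catch_error_rate = catch_error_rate,
                 cross_domain_rho = cross_domain_rho),
            class = "population_spec")
}

# rows are c(location, scale, lower, upper) on the natural scale; ambiguity
# parameters (beta_*, w_amb*, w_inter_amb*) give the magnitude, the sign is
# assigned by the aversion draw.  Domain-dependent parameters carry a
# domain suffix resolved in .pop_row().
.default_param_table <- function() {
  list(
    A      = c(1.5,   0.30,  0.5,   3.0),
    t0     = c(0.35,  0.08,  0.12,  0.8),
    z      = c(0.5,   0.05,  0.2,   0.8),
    eta    = c(0.05,  0.015, 0.005, 0.5),
    k      = c(0.02,  0.010, 0.001, 0.2),
    s      = c(1.0,   0.20,  0.3,   3.0),
    alpha  = c(0.8,   0.15,  0.2,   2.0),
    beta_itc  = c(0.25, 0.10, 0.02, 1.0),
    beta_risk = c(0.30, 0.12, 0.05, 1.0),
    w_r    = c(0.04,  0.012, 0.005, 0.15),
    w_t    = c(-0.010, 0.003, -0.05, -0.001),
    w_p    = c(3.0,   0.80,  0.5,   8.0),
    w_amb.delay        = c(0.012, 0.005, 0.002, 0.05),
    w_amb.probability  = c(1.5,   0.50,  0.2,   4.0),
    w_inter.delay       = c(-1e-4, 5e-5, -5e-4, -1e-5),
    w_inter.probability = c(-0.02, 0.008, -0.08, -0.001),
    w_inter_amb.delay       = c(-1e-4, 5e-5, -5e-4, -1e-5),
    w_inter_amb.probability = c(-0.02, 0.010, -0.08, -0.001)
  )
}

.pop_row <- function(pop, param, domain) {
  key <- paste0(param, ".", domain)
  if (!is.null(pop$params[[key]])) return(pop$params[[key]])
  if (!is.null(pop$params[[param]])) return(pop$params[[param]])
  stop("population spec has no entry for parameter ", param)
}

# inverse-CDF truncated normal; degenerate scale returns the location
.rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  pl <- pnorm(lower, mean, sd); pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

#' Sample one participant's DDM parameters
#'
#' @param pop A [population_spec()].
#' @param model Registry entry or model id.
#' @param averse Optional logical overriding the aversion draw (used to
#'   impose cross-domain correlated aversion at the cohort level).
#' @return Named list of natural-scale parameters.
#' @export
sample_participant <- function(pop, model, averse = NULL) {
  if (is.character(model)) model <- ddm_model(model)
  out <- list()
  for (nm in model$param_names) {
    r <- .pop_row(pop, nm, model$domain)
    val <- .rtnorm(1, r[1], r[2], r[3], r[4])
    if (identical(nm, model$amb_param)) {
      if (is.null(averse)) averse <- runif(1) < pop$frac_ambiguity_averse
      # averse <=> dv/dAmb < 0: sign the magnitude against amb_direction
      val <- abs(val) * (if (averse) -model$amb_direction
                         else model$amb_direction)
    }
    out[[nm]] <- val
  }
  out
}

#' Simulate one behavioural record
#'
#' Draws (choice, decision time) from the WFPT process at the trial's drift
#' rate, adds the non-decision time, then applies contaminants: with
#' probability `p_rt_outlier` the RT is replaced by a draw outside
#' \[0.3 s, 10 s\] (half below, half above); with probability
#' `p_switch_trial` the trial is marked as a preference switch and the
#' choice redrawn from the absorption probability.  Catch-trial responses
#' bypass evidence accumulation (attention, not valuation): the constant
#' option is chosen with probability `1 - catch_error_rate`.
#'
#' @param params Named natural-scale parameters (with `A`, `t0`, `z`).
#' @param model Registry entry or model id.
#' @param trial One-row trial data frame.
#' @param pop A [population_spec()] supplying contamination rates.
#' @return One-row data frame: trial columns plus `choice`, `rt`,
#'   `n_switches`, `is_rt_outlier`.
#' @export
simulate_trial <- function(params, model, trial, pop = population_spec()) {
  res <- simulate_records(params, model, trial, pop)
  res
}

# vectorised simulator over a block of trials (one participant)
simulate_records <- function(params, model, trials, pop) {
  if (is.character(model)) model <- ddm_model(model)
  n <- nrow(trials)
  choice <- character(n); rt <- numeric(n); nsw <- integer(n)
  is_catch <- trials$kind == "catch"
  if (any(!is_catch)) {
    tr <- trials[!is_catch, , drop = FALSE]
    v <- drift_rate(model, params, tr)
    ch <- character(nrow(tr)); dtv <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      d <- rwfpt(1, params$A, params$z, v[i])
      ch[i] <- if (d$upper) "variable" else "constant"
      dtv[i] <- d$dt
    }
    sw <- runif(nrow(tr)) < pop$p_switch_trial
    if (any(sw)) {
      p_up <- choice_prob_upper(params$A, params$z, v[sw])
      ch[sw] <- ifelse(runif(sum(sw)) < p_up, "variable", "constant")
    }
    choice[!is_catch] <- ch
    rt[!is_catch] <- params$t0 + dtv
    nsw[!is_catch] <- ifelse(sw, 1L + stats::rpois(nrow(tr), 0.3), 0L)
  }
  if (any(is_catch)) {
    nc <- sum(is_catch)
    choice[is_catch] <- ifelse(runif(nc) < pop$catch_error_rate,
                               "variable", "constant")
    rt[is_catch] <- params$t0 + stats::rlnorm(nc, log(0.5), 0.35)
    nsw[is_catch] <- 0L
  }
  out_mask <- runif(n) < pop$p_rt_outlier
  if (any(out_mask)) {
    k <- sum(out_mask)
    low <- runif(k) < 0.5
    rt[out_mask] <- ifelse(low, runif(k, 0.05, 0.295), runif(k, 10.01, 12))
  }
  res <- trials
  res$choice <- choice
  res$rt <- rt
  res$n_switches <- nsw
  res$is_rt_outlier <- rt < 0.3 | rt > 10
  res
}

# single-domain session: shuffled 98-trial grid in 7 blocks of 14 + 1 catch
.single_domain_session <- function(domain, seed) {
  grid <- if (domain == "delay") build_intertemporal_grid() else
    build_risky_grid()
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  grid <- grid[sample.int(nrow(grid)), ]
  blocks <- vector("list", 7L)
  for (b in seq_len(7L)) {
    blk <- grid[(b - 1L) * 14L + seq_len(14L), ]
    pos <- sample.int(15L, 1L)
    blk <- rbind(utils::head(blk, pos - 1L), .catch_trial(domain),
                 utils::tail(blk, 15L - pos))
    blk$block <- b
    blocks[[b]] <- blk
  }
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate a cohort with known ground truth
#'
#' Each participant receives a fresh session (both domains by default, 210
#' trials; or a single-domain session of 98 choice + 7 catch trials) and a
#' full behavioural table simulated from parameters drawn from `pop` under
#' the given generating models.  Aversion indicators across domains share
#' the population copula.  Reproducible: participant-level RNG streams are
#' derived from `(seed, participant)`.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Master seed.
#' @param models Named character vector mapping domain to generating model
#'   id, e.g. `c(delay = "itc_aw_amb_rxd", probability = "risk_gs")`.
#' @param pop A [population_spec()].
#' @param domains Domains to include (`"delay"`, `"probability"` or both).
#' @return List with `behavior` (per-trial records, `participant` column),
#'   `truth` (one row per participant x domain with the generating
#'   parameters) and `manifest` (seed, models, pop).
#' @export
simulate_cohort <- function(n_participants, seed,
                            models = c(delay = "itc_aw_amb_rxd",
                                       probability = "risk_gs"),
                            pop = population_spec(),
                            domains = c("delay", "probability")) {
  stopifnot(n_participants >= 1)
  domains <- match.arg(domains, c("delay", "probability"),
                       several.ok = TRUE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pseeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  beh <- list(); truth <- list()
  for (p in seq_len(n_participants)) {
    set.seed(pseeds[p])
    # correlated aversion across domains via a Gaussian copula
    xi1 <- rnorm(1)
    xi2 <- pop$cross_domain_rho * xi1 +
      sqrt(1 - pop$cross_domain_rho^2) * rnorm(1)
    thr <- qnorm(pop$frac_ambiguity_averse)
    averse <- c(delay = xi1 < thr, probability = xi2 < thr)
    sess_seed <- sample.int(2^30, 1)
    full_sess <- if (length(domains) == 2L) assemble_session(sess_seed)
                 else .single_domain_session(domains, sess_seed)
    recs <- list()
    for (dom in domains) {
      model <- ddm_model(models[[dom]])
      pars <- sample_participant(pop, model, averse = averse[[dom]])
      sess <- full_sess[full_sess$domain == dom, , drop = FALSE]
      recs[[dom]] <- simulate_records(pars, model, sess, pop)
      truth[[length(truth) + 1L]] <-
        data.frame(participant = p, domain = dom, model_id = model$model_id,
                   averse = averse[[dom]],
                   as.data.frame(pars), stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, recs)
    rec <- rec[order(rec$trial_index), , drop = FALSE]
    rec$participant <- p
    beh[[length(beh) + 1L]] <- rec
  }
  behavior <- do.call(rbind, beh)
  rownames(behavior) <- NULL
  truth <- do.call(.rbind_fill, truth)
  list(behavior = behavior, truth = truth,
       manifest = list(seed = seed, models = as.list(models), pop = pop))
}

# rbind data frames with differing columns (union schema, NA fill)
.rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  }))
}
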