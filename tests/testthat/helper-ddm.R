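# shared fixtures built in code

# one-row trial constructor with sensible defaults
make_trial <- function(domain = "delay", kind = "exact", amount = 50,
                       delay_days = 100, prob_win = 1, amb_days = 0,
                       amb_prob = 0) {
  data.frame(domain = domain, kind = kind, amount = amount,
             delay_days = delay_days, prob_win = prob_win,
             amb_days = amb_days, amb_prob = amb_prob,
             stringsAsFactors = FALSE)
}

# every ambiguity model collapses to this parent at zero ambiguity
PARENT_MODEL <- c(
  itc_hyp_add = "itc_hyp",  itc_hyp_tp = "itc_hyp",
  itc_ghyp_add = "itc_ghyp", itc_ghyp_tp = "itc_ghyp",
  itc_aw_amb = "itc_aw", itc_aw_amb_rxd = "itc_aw_rxd",
  itc_aw_amb_rxa = "itc_aw", itc_aw_full = "itc_aw_rxd",
  risk_gs = "risk_eu", risk_eu_add = "risk_eu",
  risk_aw_amb = "risk_aw", risk_aw_amb_rxp = "risk_aw_rxp",
  risk_aw_amb_rxa = "risk_aw", risk_aw_full = "risk_aw_rxp")

# mid-range drift parameter values for any model (natural scale)
default_drift_params <- function(model) {
  if (is.character(model)) model <- ddm_model(model)
  vals <- list(A = 1.5, t0 = 0.35, z = 0.5, eta = 0.05, k = 0.02, s = 1,
               alpha = 0.8, beta_itc = 0.2, beta_risk = 0.3,
               w_r = 0.04, w_t = -0.01,
               w_p = 3, w_amb = if (model$domain == "delay") -0.012 else -1.5,
               w_inter = if (model$domain == "delay") -1e-4 else -0.02,
               w_inter_amb = if (model$domain == "delay") -1e-4 else -0.02)
  vals[model$param_names]
}

# quiet single-participant synthetic dataset (no contaminants)
sim_one <- function(model_id = "itc_aw_amb_rxd", seed = 3) {
  m <- ddm_model(model_id)
  pop <- population_spec(p_rt_outlier = 0, p_switch_trial = 0)
  simulate_cohort(1, seed = seed, models = setNames(model_id, m$domain),
                  pop = pop, domains = m$domain)
}

# exact posterior draws + closed-form LOO for the conjugate normal-mean
# model: y_i ~ N(mu, 1), mu ~ N(0, tau2).  Independent oracle for PSIS-LOO.
normal_loo_fixture <- function(y, tau2 = 100, S = 4000, seed = 42) {
  n <- length(y)
  post_var <- 1 / (n + 1 / tau2)
  post_mean <- post_var * sum(y)
  set.seed(seed)
  mu <- rnorm(S, post_mean, sqrt(post_var))
  ll <- vapply(y, function(yi) dnorm(yi, mu, 1, log = TRUE),
               numeric(S))
  exact <- vapply(seq_len(n), function(i) {
    v_i <- 1 / (n - 1 + 1 / tau2)
    m_i <- v_i * sum(y[-i])
    dnorm(y[i], m_i, sqrt(v_i + 1), log = TRUE)
  }, numeric(1))
  list(ll = ll, exact = exact)
}
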