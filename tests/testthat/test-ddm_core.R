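test_that("drift-rate formulas reproduce hand-computed values", {
  tr <- make_trial(amount = 50, delay_days = 100)
  expect_equal(drift_rate("itc_aw", list(w_r = 0.1, w_t = -0.02), tr),
               0.1 * (50 - 5) + (-0.02) * 100)
  expect_equal(drift_rate("itc_hyp", list(eta = 1, k = 0), tr), 45)
  # strict printed form puts the variable amount in the sooner term
  expect_equal(drift_rate("itc_hyp", list(eta = 1, k = 0), tr,
                          strict_printed = TRUE), 0)
  # interaction model: linear arithmetic
  expect_equal(
    drift_rate("itc_aw_amb_rxd",
               list(w_r = 0.1, w_t = -0.02, w_inter = -1e-4, w_amb = -0.01),
               make_trial(kind = "ambiguous", amount = 22, amb_days = 148)),
    0.1 * 17 - 0.02 * 100 - 1e-4 * 17 * 100 - 0.01 * 74)
  # risky: Gilboa-Schmeidler shifts the perceived probability
  trr <- make_trial(domain = "probability", kind = "ambiguous", amount = 36,
                    delay_days = 0, prob_win = 0.5, amb_prob = 0.74)
  expect_equal(drift_rate("risk_gs", list(eta = 0.05, alpha = 0.8,
                                          beta_risk = 0.3), trr),
               0.05 * ((0.5 - 0.3 * 0.37) * 36^0.8 - 5^0.8))
})

test_that("zero ambiguity collapses every ambiguity model onto its parent", {
  for (mid in names(PARENT_MODEL)) {
    m <- ddm_model(mid)
    parent <- ddm_model(PARENT_MODEL[[mid]])
    grid <- if (m$domain == "delay") build_intertemporal_grid() else
      build_risky_grid()
    grid$amb_days <- 0; grid$amb_prob <- 0
    p <- default_drift_params(m)
    expect_equal(drift_rate(m, p, grid),
                 drift_rate(parent, p[parent$param_names], grid),
                 tolerance = 1e-12, label = mid)
  }
})

test_that("ambiguity aversion makes drift decrease in the ambiguity level", {
  lv <- c(0, 48, 100, 148, 200)
  tr <- make_trial(kind = "ambiguous", amount = rep(29, 5), amb_days = lv)
  v <- drift_rate("itc_aw_amb", list(w_r = 0.04, w_t = -0.01,
                                     w_amb = -0.012), tr)
  expect_true(all(diff(v) < 0))
  # finite-difference slope matches the formula coefficient (w_amb / 2)
  expect_equal(diff(v) / diff(lv), rep(-0.012 / 2, 4))
})

test_that("WFPT densities integrate to one and obey reflection symmetry", {
  for (ps in list(c(A = 1, z = 0.5, v = 0.5), c(A = 2, z = 0.3, v = -1),
                  c(A = 1.5, z = 0.6, v = 2))) {
    up <- integrate(function(t)
      exp(wfpt_logpdf(t, "upper", ps["A"], 0, ps["z"], ps["v"])),
      0, Inf, rel.tol = 1e-9)$value
    lo <- integrate(function(t)
      exp(wfpt_logpdf(t, "lower", ps["A"], 0, ps["z"], ps["v"])),
      0, Inf, rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-6)
    # upper-boundary mass equals the closed-form absorption probability
    expect_equal(up, choice_prob_upper(ps["A"], ps["z"], ps["v"]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    ts <- c(0.1, 0.5, 1, 2)
    expect_equal(
      wfpt_logpdf(ts, "upper", ps["A"], 0, ps["z"], ps["v"]),
      wfpt_logpdf(ts, "lower", ps["A"], 0, 1 - ps["z"], -ps["v"]))
  }
})

test_that("choice probability has the v->0 limit z and the z=0.5 symmetry", {
  expect_equal(choice_prob_upper(1, 0.5, 0), 0.5)
  expect_equal(choice_prob_upper(2, 0.3, 1e-12), 0.3, tolerance = 1e-9)
  for (v in c(0.2, 1, 3))
    expect_equal(choice_prob_upper(1.7, 0.5, v) +
                   choice_prob_upper(1.7, 0.5, -v), 1, tolerance = 1e-12)
  expect_equal(choice_prob_upper(2, 0.5, 1),
               (exp(-2) - 1) / (exp(-4) - 1), tolerance = 1e-12)
})

test_that("series density agrees with an Euler-Maruyama simulation oracle", {
  A <- 1; z <- 0.5; v <- 1
  set.seed(99)
  sim <- rwfpt_euler(20000, A, z, v, dt = 1e-4)
  p_up <- choice_prob_upper(A, z, v)
  se <- sqrt(p_up * (1 - p_up) / nrow(sim))
  expect_lt(abs(mean(sim$upper) - p_up), 4 * se + 0.01)
  # conditional RT quantiles of the upper-boundary arm
  qf <- ambiddm:::.wfpt_cond_quantile_fun(A, z, v, upper = TRUE)
  emp <- quantile(sim$dt[sim$upper], c(0.25, 0.5, 0.75))
  expect_equal(unname(emp), qf(c(0.25, 0.5, 0.75)), tolerance = 0.04)
})

test_that("mean decision time matches the closed form at z = 0.5", {
  set.seed(7)
  for (ps in list(c(A = 1.5, v = 1), c(A = 1, v = 0.3))) {
    s <- rwfpt(20000, ps["A"], 0.5, ps["v"])
    mu <- mean_decision_time(ps["A"], ps["v"])
    expect_lt(abs(mean(s$dt) - mu), 4 * sd(s$dt) / sqrt(nrow(s)) + 0.005)
  }
})

test_that("trial likelihood switches between WFPT and choice-only forms", {
  p <- list(A = 1.5, t0 = 0.3, z = 0.5, w_r = 0.04, w_t = -0.01)
  tr <- make_trial(amount = 36, delay_days = 50)
  rec <- cbind(tr, choice = "variable", rt = 0.9, n_switches = 0L)
  v <- drift_rate("itc_aw", p, tr)
  expect_equal(trial_loglik(rec, "itc_aw", p),
               wfpt_logpdf(0.9, "upper", p$A, p$t0, p$z, v))
  # switch trial: choice-only likelihood, normalised over both choices
  rec_sw <- rec; rec_sw$n_switches <- 2L
  expect_equal(trial_loglik(rec_sw, "itc_aw", p),
               log(choice_prob_upper(p$A, p$z, v)))
  rec_sw2 <- rec_sw; rec_sw2$choice <- "constant"
  expect_equal(exp(trial_loglik(rec_sw, "itc_aw", p)) +
                 exp(trial_loglik(rec_sw2, "itc_aw", p)), 1)
  # impossible observation: rt at or below t0
  rec_fast <- rec; rec_fast$rt <- 0.2
  expect_equal(trial_loglik(rec_fast, "itc_aw", p), -Inf)
  # excluded trials refuse a likelihood
  rec_out <- rec; rec_out$is_rt_outlier <- TRUE
  expect_error(trial_loglik(rec_out, "itc_aw", p), "outlier")
  # domain mismatch is an error
  expect_error(drift_rate("risk_eu", list(eta = 1, alpha = 1), tr),
               "domain")
})
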