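test_that("degenerate population collapses onto the location vector", {
  zero <- lapply(ambiddm:::.default_param_table(), function(r)
    c(r[1], 0, r[3], r[4]))
  pop <- population_spec(params = zero, frac_ambiguity_averse = 1)
  m <- ddm_model("itc_aw_amb")
  set.seed(1)
  p1 <- sample_participant(pop, m)
  p2 <- sample_participant(pop, m)
  expect_equal(p1, p2)
  expect_equal(p1$w_r, 0.04)
  # frac_ambiguity_averse = 1: every ambiguity effect reduces drift toward
  # the variable option
  expect_true(p1$w_amb * m$amb_direction < 0)
})

test_that("aversion fraction matches the population default", {
  pop <- population_spec()     # frac_ambiguity_averse = 0.70
  m <- ddm_model("itc_aw_amb_rxd")
  set.seed(20)
  averse <- replicate(1000, {
    p <- sample_participant(pop, m)
    p$w_amb * m$amb_direction < 0
  })
  ci <- qbinom(c(0.0005, 0.9995), 1000, 0.70) / 1000
  expect_gte(mean(averse), ci[1])
  expect_lte(mean(averse), ci[2])
})

test_that("simulated choices follow the absorption probability", {
  set.seed(5)
  # extreme drift: the variable option is (almost) always chosen
  s <- rwfpt(10000, 1.5, 0.5, 50)
  expect_gte(mean(s$upper), 0.999)
  # moderate drift: empirical fraction within 3 Monte-Carlo SEs
  s2 <- rwfpt(20000, 1.5, 0.45, 0.6)
  p <- choice_prob_upper(1.5, 0.45, 0.6)
  expect_lt(abs(mean(s2$upper) - p), 3 * sqrt(p * (1 - p) / 20000) + 1e-3)
})

test_that("clean cohorts have no contaminants and survive preprocessing", {
  coh <- sim_one("itc_aw_amb_rxd", seed = 9)
  b <- coh$behavior
  expect_false(any(b$is_rt_outlier))
  expect_true(all(b$n_switches == 0))
  rep <- apply_exclusions(b)
  expect_true(all(rep$included_ddm))
  expect_equal(nrow(ddm_ready_trials(b, rep)), sum(b$kind != "catch"))
})

test_that("cohort simulation is reproducible and fully documented", {
  coh1 <- simulate_cohort(2, seed = 7)
  coh2 <- simulate_cohort(2, seed = 7)
  expect_identical(coh1$behavior, coh2$behavior)
  expect_identical(coh1$truth, coh2$truth)
  # default two-domain session: 210 records per participant, 14 catch
  b1 <- coh1$behavior[coh1$behavior$participant == 1, ]
  expect_equal(nrow(b1), 210)
  expect_equal(sum(b1$kind == "catch"), 14)
  # ground truth: one row per participant and domain, params recorded
  expect_equal(nrow(coh1$truth), 4)
  expect_true(all(ddm_model("itc_aw_amb_rxd")$param_names %in%
                    names(coh1$truth)))
  expect_true(all(ddm_model("risk_gs")$param_names %in% names(coh1$truth)))
})

test_that("mean simulated RT decreases as |drift| increases", {
  set.seed(11)
  mean_dt <- vapply(c(0.2, 0.8, 1.6, 3), function(v)
    mean(rwfpt(4000, 1.5, 0.5, v)$dt), numeric(1))
  expect_true(all(diff(mean_dt) < 0))
})

test_that("contaminant rates produce the expected record mix", {
  pop <- population_spec(p_rt_outlier = 0.5, p_switch_trial = 0.4,
                         catch_error_rate = 1)
  coh <- simulate_cohort(1, seed = 13, models = c(delay = "itc_aw"),
                         pop = pop, domains = "delay")
  b <- coh$behavior
  n <- nrow(b)
  expect_gt(sum(b$is_rt_outlier), n * 0.5 - 3 * sqrt(n * 0.25))
  expect_true(all(b$rt[b$is_rt_outlier] < 0.3 | b$rt[b$is_rt_outlier] > 10))
  sw <- b$n_switches[b$kind != "catch"]
  expect_gt(mean(sw >= 1), 0.4 - 3 * sqrt(0.24 / length(sw)))
  expect_true(all(b$choice[b$kind == "catch"] == "variable"))
})
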