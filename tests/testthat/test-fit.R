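test_that("the sampler is deterministic under a fixed seed", {
  lp <- function(th) sum(dnorm(th, c(1, -2), c(1, 0.5), log = TRUE))
  r1 <- mcmc_sample(lp, 2, n_chains = 2, n_warmup = 200, n_sampling = 200,
                    seed = 4)
  r2 <- mcmc_sample(lp, 2, n_chains = 2, n_warmup = 200, n_sampling = 200,
                    seed = 4)
  expect_identical(r1$chains, r2$chains)
  draws <- do.call(rbind, r1$chains)
  expect_equal(colMeans(draws), c(1, -2), tolerance = 0.15)
  expect_equal(apply(draws, 2, sd), c(1, 0.5), tolerance = 0.2)
})

test_that("split-Rhat separates converged from divergent chains", {
  set.seed(1)
  same <- matrix(rnorm(2000), 1000, 2)
  expect_lt(max(split_rhat(list(same, same))), 1.01)
  far <- same + 10
  expect_gt(max(split_rhat(list(same, far))), 2)
  expect_error(split_rhat(list(same)), "2 chains")
})

test_that("log posterior is finite at the prior means for every model", {
  coh_d <- sim_one("itc_aw", seed = 21)
  coh_p <- sim_one("risk_aw", seed = 22)
  for (mid in list_models()$model_id) {
    m <- ddm_model(mid)
    b <- if (m$domain == "delay") coh_d$behavior else coh_p$behavior
    b <- b[b$kind != "catch", ]
    lp <- ambiddm:::.ddm_logpost_factory(b, m, 5)
    expect_true(is.finite(lp(rep(0, length(m$param_names)))), label = mid)
  }
})

test_that("a synthetic participant is fitted with converged chains", {
  coh <- sim_one("itc_aw_amb_rxd", seed = 3)
  fit <- fit_participant(coh$behavior, "itc_aw_amb_rxd",
                         mcmc_config(n_warmup = 400, n_sampling = 400,
                                     seed = 2),
                         participant = 1)
  cc <- check_convergence(fit)
  expect_lt(cc$max_rhat, 1.02)
  expect_equal(ncol(fit$pointwise_loglik), 98)  # all retained trials
  expect_equal(nrow(fit$pointwise_loglik), 800)
  expect_true(all(is.finite(fit$pointwise_loglik)))
  # same data + config + seed: identical draws
  fit2 <- fit_participant(coh$behavior, "itc_aw_amb_rxd",
                          mcmc_config(n_warmup = 400, n_sampling = 400,
                                      seed = 2))
  expect_identical(fit$draws, fit2$draws)
  # posterior means near the generating truth (weak sanity bound)
  truth <- coh$truth
  expect_equal(unname(colMeans(fit$draws)[c("A", "t0")]),
               c(truth$A, truth$t0), tolerance = 0.25)
})

test_that("too few usable trials refuse a fit", {
  coh <- sim_one("itc_aw_amb_rxd", seed = 4)
  b <- coh$behavior[1:40, ]
  expect_error(fit_participant(b, "itc_aw_amb_rxd"), "usable trials")
})

test_that("degenerate truth variance is reported, not correlated", {
  zero <- lapply(ambiddm:::.default_param_table(), function(r)
    c(r[1], 0, r[3], r[4]))
  pop <- population_spec(params = zero, frac_ambiguity_averse = 1,
                         p_rt_outlier = 0, p_switch_trial = 0)
  rec <- recover_parameters("itc_aw", n_participants = 10,
                            cfg = mcmc_config(n_warmup = 150,
                                              n_sampling = 150, seed = 1),
                            pop = pop, seed = 5)
  expect_true(all(rec$table$degenerate))
  expect_true(all(is.na(rec$table$r)))
})
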