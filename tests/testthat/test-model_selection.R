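test_that("PSIS-LOO matches the conjugate exact-LOO oracle", {
  set.seed(31)
  y <- rnorm(10, 0.5, 1)
  fx <- normal_loo_fixture(y)
  res <- psis_loo(fx$ll)
  expect_equal(res$pointwise, fx$exact, tolerance = 0.02)
  expect_equal(res$elpd_loo, sum(fx$exact), tolerance = 0.05)
  # well-specified model: tame importance ratios
  expect_true(all(res$pareto_k < 0.7))
  expect_equal(res$elpd_loo, sum(res$pointwise))
})

test_that("identical draws collapse PSIS-LOO to the exact log likelihood", {
  ll <- matrix(rep(c(-1.2, -0.8, -2), each = 200), 200, 3)
  expect_warning(res <- psis_loo(ll), "identical")
  expect_equal(res$pointwise, c(-1.2, -0.8, -2))
  expect_error(psis_loo(ll[1:50, ]), "100 draws")
})

test_that("unsmoothed IS-LOO and PSIS-LOO agree on easy problems", {
  set.seed(8)
  fx <- normal_loo_fixture(rnorm(12))
  expect_equal(psis_loo(fx$ll)$pointwise, exact_loo_pointwise(fx$ll),
               tolerance = 0.02)
})

test_that("Akaike-type weights obey softmax identities", {
  expect_equal(akaike_weights(c(-100, -100, -100)), rep(1 / 3, 3))
  expect_equal(akaike_weights(c(-5, -7)), akaike_weights(c(5, 3)))
  w <- akaike_weights(c(log(4), 0))
  expect_equal(w[1] / w[2], 4)
  expect_error(akaike_weights(c(1, NA)))
  expect_error(akaike_weights(3))
})

test_that("pseudo-inclusion Bayes factors follow the odds arithmetic", {
  r <- pbf_inclusion(c(0.4, 0.4, 0.1, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$pbf, 4)
  # uniform weights: PBF 1 for any partition
  expect_equal(pbf_inclusion(rep(0.25, 4), c(TRUE, FALSE, TRUE, FALSE))$pbf,
               1)
  expect_equal(pbf_inclusion(rep(1 / 3, 3), c(TRUE, FALSE, FALSE))$pbf, 1)
  # inverted partition flips the sign of log PBF
  a <- pbf_inclusion(c(0.7, 0.2, 0.1), c(TRUE, TRUE, FALSE))
  b <- pbf_inclusion(c(0.7, 0.2, 0.1), c(FALSE, FALSE, TRUE))
  expect_equal(a$log_pbf, -b$log_pbf)
  # empty out-group: capped sentinel
  cap <- pbf_inclusion(c(1, 0), c(TRUE, FALSE))
  expect_true(cap$capped)
  expect_error(pbf_inclusion(c(0.5, 0.5), c(TRUE, TRUE)), "non-empty")
})

test_that("feature labels match the registry", {
  ids <- c("itc_hyp", "itc_aw_amb_rxd", "risk_gs", "risk_aw")
  expect_equal(unname(model_feature(ids, "ambiguity")),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(unname(model_feature(ids, "attribute_wise")),
               c(FALSE, TRUE, FALSE, TRUE))
})

test_that("random-effects BMS is symmetric, equivariant and decisive", {
  # identical evidence: symmetric PXP, substantial omnibus risk that grows
  # with the sample (the null gains support as more subjects tie)
  L <- matrix(-180, 6, 2)
  r <- re_bms(L, n_samples = 2e4, seed = 1)
  expect_equal(r$pxp, c(0.5, 0.5), tolerance = 0.02)
  expect_gt(r$bor, 0.5)
  r_big <- re_bms(matrix(-180, 60, 2), n_samples = 2e4, seed = 1)
  expect_gt(r_big$bor, r$bor)
  # a model uniformly better by 10 nats for 20 participants dominates
  L2 <- cbind(rep(-180, 20), rep(-170, 20), rep(-181, 20))
  r2 <- re_bms(L2, n_samples = 5e4, seed = 1)
  expect_gt(r2$pxp[2], 0.95)
  expect_equal(which.max(r2$expected_freq), 2L)
  # permuting columns permutes the result
  r3 <- re_bms(L2[, c(2, 1, 3)], n_samples = 5e4, seed = 1)
  expect_equal(r3$pxp[1], r2$pxp[2], tolerance = 0.01)
  expect_error(re_bms(L2[1, , drop = FALSE]), "2 subjects")
})

test_that("compare_models assembles weights and per-participant PBFs", {
  elpd <- cbind(itc_aw_amb = c(-180, -170), itc_aw = c(-182, -175))
  cm <- compare_models(elpd, "ambiguity")
  expect_equal(rowSums(cm$weights), c(1, 1))
  expect_equal(cm$pbf$log_pbf, c(2, 5), tolerance = 1e-9)
  expect_equal(unname(cm$in_group), c(TRUE, FALSE))
})
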