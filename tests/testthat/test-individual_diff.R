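test_that("ambiguity-preference classification follows the posterior sign", {
  expect_equal(classify_ambiguity_preference(rnorm(2000, -3, 0.5)), "averse")
  expect_equal(classify_ambiguity_preference(rnorm(2000, 3, 0.5)), "seeking")
  set.seed(2)
  sym <- c(rnorm(1000, -1), rnorm(1000, 1))
  expect_equal(classify_ambiguity_preference(sym, threshold = 0.6),
               "indeterminate")
  # fits of non-ambiguity models cannot be classified
  fake <- structure(list(model_id = "itc_aw",
                         draws = matrix(0, 10, 1)), class = "ddm_fit")
  expect_error(classify_ambiguity_preference(fake), "no ambiguity term")
  # oriented extraction from a fit: negative w_amb draws mean aversion
  fake2 <- structure(list(model_id = "itc_aw_amb_rxd",
                          draws = matrix(rnorm(400, -0.01, 0.001), 100, 4,
                                         dimnames = list(NULL,
                                           c("w_r", "w_t", "w_inter",
                                             "w_amb")))),
                     class = "ddm_fit")
  expect_equal(classify_ambiguity_preference(fake2), "averse")
})

test_that("HDI is the shortest interval with the requested mass", {
  set.seed(3)
  x <- rnorm(20000)
  h <- hdi(x)
  expect_equal(h, c(-1.96, 1.96), tolerance = 0.05)
  expect_lt(diff(hdi(x, 0.5)), diff(h))
  # skewed posterior: HDI is shorter than the equal-tail interval
  y <- rgamma(20000, 2, 1)
  expect_lt(diff(hdi(y)), diff(quantile(y, c(0.025, 0.975))))
})

test_that("the ROPE rule yields the three printed verdicts", {
  rope <- c(-0.06, 0.06)
  expect_equal(rope_decision(runif(2000, 0.2, 0.3), rope)$verdict,
               "significant")
  expect_equal(rope_decision(runif(2000, -0.01, 0.01), rope)$verdict,
               "practically_equivalent")
  expect_equal(rope_decision(runif(2000, -0.05, 0.20), rope)$verdict,
               "inconclusive")
  expect_error(rope_decision(rnorm(100), c(0.1, -0.1)), "ROPE")
})

test_that("ROPE verdicts are order-invariant and monotone in width", {
  set.seed(4)
  draws <- rnorm(5000, 0.1, 0.02)
  v1 <- rope_decision(draws, c(-0.01, 0.01))$verdict
  v2 <- rope_decision(sample(draws), c(-0.01, 0.01))$verdict
  expect_equal(v1, v2)
  rank <- c(significant = 1, inconclusive = 2, practically_equivalent = 3)
  widths <- c(0.01, 0.06, 0.2, 0.5)
  verdicts <- vapply(widths, function(w)
    rope_decision(draws, c(-w, w))$verdict, "")
  expect_true(all(diff(rank[verdicts]) >= 0))
})

test_that("robust correlation recovers dependence and resists outliers", {
  set.seed(6)
  x <- rnorm(100)
  perfect <- robust_correlation(x, x + rnorm(100, 0, 1e-3), seed = 1)
  expect_gt(mean(perfect$rho > 0.95), 0.99)
  # bivariate normal with rho = 0.5
  n <- 500
  x2 <- rnorm(n); y2 <- 0.5 * x2 + sqrt(1 - 0.25) * rnorm(n)
  rc <- robust_correlation(x2, y2, seed = 2)
  expect_lt(abs(rc$mean_rho - 0.5), 0.1)
  expect_lt(max(rc$rhat), 1.05)
  # 5% gross outliers: the posterior mean moves less than Pearson does
  xo <- x2; yo <- y2
  idx <- 1:25
  xo[idx] <- rnorm(25, 8, 0.5); yo[idx] <- rnorm(25, -8, 0.5)
  rco <- robust_correlation(xo, yo, seed = 3)
  pearson_shift <- abs(cor(xo, yo) - cor(x2, y2))
  robust_shift <- abs(rco$mean_rho - rc$mean_rho)
  expect_lt(robust_shift, pearson_shift)
  expect_error(robust_correlation(x2, rep(1, n)), "variance")
  expect_error(robust_correlation(1:5, 1:5), "n >= 10")
})

test_that("cross-domain report correlates standardised paired quantities", {
  set.seed(9)
  q <- data.frame(participant = 1:60,
                  log_pbf_delay = rnorm(60),
                  log_pbf_probability = rnorm(60))
  q$log_pbf_probability <- q$log_pbf_delay  # identical inputs
  rep <- cross_domain_report(q, seed = 1)
  expect_gt(rep$log_pbf$cor$mean_rho, 0.95)
  expect_equal(rep$log_pbf$rope$verdict, "significant")
  expect_error(cross_domain_report(q[1:5, ]), "10 participants")
})
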