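test_that("observer_params validates its domain", {
  p <- observer_params(3, 8, 0.6)
  expect_s3_class(p, "observer_params")
  expect_identical(p$sigma_m, 0)
  expect_error(observer_params(-1, 8, 0.5), "sigma_v")
  expect_error(observer_params(3, 0, 0.5), "sigma_p")
  expect_error(observer_params(3, 8, 1.2), "p_prior")
  expect_error(observer_params(3, 8, 0.5, -1), "sigma_m")
  expect_error(observer_params(NA, 8, 0.5))
})

test_that("trial_stimulus enforces the reachable range and derives disparity", {
  s <- trial_stimulus(-15, 25)
  expect_equal(s$disparity, 40)
  expect_error(trial_stimulus(95, 0), "90")
  expect_error(trial_stimulus(0, -91), "90")
})

test_that("fusion weights are reliability ratios summing to one", {
  w <- fusion_weights(1, 2)
  expect_equal(w$w_v, 0.8)
  expect_equal(w$w_v + w$w_p, 1)
  # equal noise -> equal weights
  expect_equal(fusion_weights(5, 5)$w_v, 0.5)
  # weights depend only on the noise ratio
  expect_equal(fusion_weights(2, 6)$w_v, fusion_weights(1, 3)$w_v)
})

test_that("forced fusion interpolates between the samples", {
  expect_equal(forced_fusion_estimate(10, 0, 1, 2), 8)
  x <- forced_fusion_estimate(c(10, -10), c(0, 0), 3, 3)
  expect_equal(x, c(5, -5))
  # degenerate visual noise dominance
  expect_lt(abs(forced_fusion_estimate(10, 0, 1e-3, 10) - 10), 1e-4)
})

test_that("the worked posterior example reproduces ~0.910", {
  p <- observer_params(5, 5, 0.5)
  post <- common_cause_posterior(0, 0, p)
  expect_equal(post$p_com, 0.910, tolerance = 1e-3)
  expect_equal(post$alpha, 180 * sqrt(2 * pi * 50))
})

test_that("posterior matches the grid-integration oracle on a spot check", {
  p <- observer_params(4, 7, 0.35)
  for (d in c(0, 10, 30)) {
    got <- common_cause_posterior(d / 2, -d / 2, p)$p_com
    expect_equal(got, oracle_pcom(d / 2, -d / 2, 4, 7, 0.35), tolerance = 1e-4)
  }
})

test_that("posterior is monotone decreasing in the cue conflict", {
  p <- observer_params(3, 6, 0.6)
  deltas <- seq(0, 60, by = 5)
  pc <- common_cause_posterior(deltas, rep(0, length(deltas)), p)$p_com
  expect_true(all(diff(pc) < 0))
})

test_that("prior limits pin the posterior and the estimate", {
  p0 <- observer_params(3, 6, 0)
  post0 <- common_cause_posterior(20, -5, p0)
  expect_equal(post0$p_com, 0)
  expect_equal(post0$s_hat_p, -5) # pure proprioception
  p1 <- observer_params(3, 6, 1)
  post1 <- common_cause_posterior(20, -5, p1)
  expect_equal(post1$p_com, 1)
  expect_equal(post1$s_hat_p, post1$x_ff) # forced fusion
})

test_that("position estimate is the p_com-weighted model average", {
  p <- observer_params(4, 8, 0.7)
  post <- position_estimate(12, -3, p)
  expect_equal(post$s_hat_p, post$p_com * post$x_ff + (1 - post$p_com) * -3)
  expect_true(post$s_hat_p > min(-3, post$x_ff) - 1e-12 &&
                post$s_hat_p < max(-3, post$x_ff) + 1e-12)
})

test_that("extreme conflicts stay numerically finite", {
  p <- observer_params(0.5, 0.5, 0.999)
  post <- common_cause_posterior(80, -80, p)
  expect_true(is.finite(post$p_com))
  expect_gte(post$p_com, 0)
  expect_lte(post$p_com, 1)
})

test_that("sensory sampling is seed-reproducible and unclipped", {
  st <- trial_stimulus(0, 40)
  p <- observer_params(2, 5, 0.5)
  a <- sample_sensory(st, p, 7)
  b <- sample_sensory(st, p, 7)
  expect_identical(a, b)
  expect_false(identical(a, sample_sensory(st, p, 8)))
  # large noise can leave the stimulus range (no clipping)
  big <- observer_params(200, 200, 0.5)
  draws <- vapply(1:50, function(s) sample_sensory(st, big, s)$x_v, numeric(1))
  expect_true(any(abs(draws) > 90))
})
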