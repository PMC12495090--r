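test_that("predicted error densities respect the model limits", {
  # proprioceptive limit: no integration, no motor noise -> mass at 0
  seg <- observer_params(2, 8, 0, sigma_m = 0)
  f <- predict_error_density(seg, 40, n_sim = 10000, seed = 1)
  x <- attr(f, "samples")
  expect_lt(mean(abs(x)), 0.5)
  # visual capture: density centered at -disparity
  cap <- observer_params(1e-3, 10, 1)
  f2 <- predict_error_density(cap, 40, n_sim = 10000, seed = 1)
  expect_equal(mean(attr(f2, "samples")), -40, tolerance = 0.1)
  expect_gt(f2(-40), f2(0))
  expect_error(predict_error_density(cap, 40, n_sim = 500, seed = 1), "1000")
})

test_that("densities are deterministic given the seed", {
  p <- observer_params(3, 7, 0.6, sigma_m = 1)
  q <- seq(-30, 10, length.out = 101)
  f1 <- predict_error_density(p, 20, n_sim = 2000, seed = 9)
  f2 <- predict_error_density(p, 20, n_sim = 2000, seed = 9)
  expect_identical(f1(q), f2(q))
  f3 <- predict_error_density(p, 20, n_sim = 2000, seed = 10)
  expect_false(identical(f1(q), f3(q)))
})

test_that("loglik conventions: empty sum, normalization precondition, order", {
  p <- observer_params(3, 7, 0.6, sigma_m = 1)
  empty <- data.frame(disparity_deg = numeric(0),
                      normalized_error_deg = numeric(0))
  expect_identical(vpd_loglik(empty, p, seed = 1), 0)
  raw <- data.frame(disparity_deg = c(0, 20), observed_error_deg = c(1, -3))
  expect_error(vpd_loglik(raw, p, seed = 1), "normalize")
  tr <- simulate_vpd(build_vpd_design(1), p, 5)
  ll <- vpd_loglik(tr, p, n_sim = 2000, seed = 3)
  shuffled <- tr[with_seed(1, sample.int(nrow(tr))), ]
  expect_equal(vpd_loglik(shuffled, p, n_sim = 2000, seed = 3), ll)
  expect_identical(vpd_loglik(tr, p, n_sim = 2000, seed = 3), ll)
})

test_that("a trial at the density mode outscores one in the far tail", {
  p <- observer_params(3, 7, 0.6, sigma_m = 1)
  at_mode <- data.frame(disparity_deg = 0, normalized_error_deg = 0)
  in_tail <- data.frame(disparity_deg = 0, normalized_error_deg = 60)
  expect_gt(vpd_loglik(at_mode, p, n_sim = 2000, seed = 1),
            vpd_loglik(in_tail, p, n_sim = 2000, seed = 1))
})

test_that("the truth beats a doubled sigma_p in most seeded replicates", {
  p_true <- observer_params(2, 8, 0.7, sigma_m = 1)
  p_bad <- observer_params(2, 16, 0.7, sigma_m = 1)
  wins <- vapply(1:50, function(s) {
    tr <- simulate_vpd(build_vpd_design(s), p_true, derive_seed(s, 7L))
    vpd_loglik(tr, p_true, n_sim = 2000, seed = s) >=
      vpd_loglik(tr, p_bad, n_sim = 2000, seed = s)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("fit_participant validates its contract", {
  p <- observer_params(3, 7, 0.6)
  tr <- simulate_vpd(build_vpd_design(2), p, 3)
  expect_error(fit_participant(tr[1:10, ], seed = 1), "30 trials")
  expect_error(fit_participant(tr[, "disparity_deg", drop = FALSE], seed = 1))
  bad_bounds <- default_fit_bounds(); bad_bounds$sigma_v <- c(5, 2)
  expect_error(fit_participant(tr, bounds = bad_bounds, seed = 1), "bounds")
  neg <- default_fit_bounds(); neg$sigma_p <- c(-1, 10)
  expect_error(fit_participant(tr, bounds = neg, seed = 1), "positive")
  # bounds admitting no initial guess are rejected up front
  off <- default_fit_bounds(); off$sigma_v <- c(25, 30)
  expect_error(fit_participant(tr, bounds = off, seed = 1),
               "initial guess")
})

test_that("a quick fit recovers a strong integrator and stays in bounds", {
  p <- observer_params(2, 8, 0.9, sigma_m = 1)
  tr <- simulate_vpd(build_vpd_design(5), p, 11)
  fit <- fit_participant(tr, n_starts = 2, n_sim = 2000, seed = 21,
                         sigma_m = 1, maxit = 300, pool = 10)
  expect_s3_class(fit, "fit_result")
  expect_true(fit$converged)
  b <- default_fit_bounds()
  expect_true(fit$sigma_v_hat >= b$sigma_v[1] && fit$sigma_v_hat <= b$sigma_v[2])
  expect_true(fit$sigma_p_hat >= b$sigma_p[1] && fit$sigma_p_hat <= b$sigma_p[2])
  expect_true(fit$p_prior_hat >= 0 && fit$p_prior_hat <= 1)
  expect_true(is.finite(fit$loglik))
  # sigma_p in the right region and the fit is reproducible
  expect_lt(abs(fit$sigma_p_hat - 8) / 8, 0.5)
  expect_identical(fit, fit_participant(tr, n_starts = 2, n_sim = 2000,
                                        seed = 21, sigma_m = 1, maxit = 300,
                                        pool = 10))
})

test_that("near-boundary priors are recovered as near-boundary", {
  p <- observer_params(2, 8, 0, sigma_m = 1.5)
  tr <- simulate_vpd(build_vpd_design(6), p, 13)
  fit <- fit_participant(tr, n_starts = 4, n_sim = 2000, seed = 22,
                         sigma_m = 1.5, maxit = 300, pool = 30)
  expect_lt(fit$p_prior_hat, 0.1)
})

test_that("degenerate recovery grids are flagged instead of correlated", {
  one <- data.frame(sigma_v = rep(2, 3), sigma_p = rep(8, 3),
                    p_prior = rep(0.7, 3), sigma_m = rep(1, 3))
  res <- recovery_experiment(one, n_sim = 1500, n_starts = 1, seed = 2,
                             sigma_m_fit = 1, maxit = 60)
  expect_true(res$degenerate)
  expect_true(all(is.na(res$summary$correlation)))
  expect_equal(nrow(res$fits), 3)
  expect_error(recovery_experiment(one[0, ]), "empty")
})
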