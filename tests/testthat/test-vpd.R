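test_that("the three-block design has the printed structure", {
  d <- build_vpd_design(1)
  expect_equal(nrow(d), 49 + 49 + 25)
  b1 <- d[d$block == 1, ]
  expect_equal(sort(unique(b1$target_deg)), c(-45, -30, -15, 0, 15, 30, 45))
  expect_equal(sort(unique(b1$disparity_deg)),
               c(-40, -26.6, -13.3, 0, 13.3, 26.6, 40))
  expect_equal(nrow(unique(b1[, c("target_deg", "disparity_deg")])), 49)
  b3 <- d[d$block == 3, ]
  expect_equal(sort(unique(b3$disparity_deg)), c(-40, -20, 0, 20, 40))
  expect_length(unique(b3$target_deg), 5)
  expect_true(all(b3$collect_rating))
  expect_false(any(d$collect_rating[d$block != 3]))
})

test_that("design order is randomized but seed-stable", {
  expect_identical(build_vpd_design(5), build_vpd_design(5))
  d1 <- build_vpd_design(5); d2 <- build_vpd_design(6)
  expect_false(identical(d1$target_deg, d2$target_deg))
  expect_error(build_vpd_design(1, block3_targets = c(0, 1, 2, 3, 4)),
               "targets")
})

test_that("simulated sessions are reproducible and normalized", {
  p <- observer_params(3, 7, 0.6, sigma_m = 1)
  d <- build_vpd_design(2)
  t1 <- simulate_vpd(d, p, 11)
  expect_identical(t1, simulate_vpd(d, p, 11))
  expect_equal(mean(t1$normalized_error_deg[t1$disparity_deg == 0]), 0)
  expect_true(all(is.na(t1$rating[t1$block != 3])))
  r3 <- t1$rating[t1$block == 3]
  expect_true(all(r3 %in% 1:10))
})

test_that("errors drift opposite the disparity in proportion to integration", {
  d <- build_vpd_design(3)
  strong <- observer_params(1, 10, 0.95)
  tr <- simulate_vpd(d, strong, 21)
  m <- tapply(tr$normalized_error_deg, tr$disparity_deg, mean)
  lv <- as.numeric(names(m))
  # mean error is negatively related to disparity (the attraction slope is
  # diluted at the largest disparities, where p_com drops)
  expect_lt(sum(m * lv) / sum(lv^2), -0.2)
  # non-integrating observer shows no drift
  seg <- observer_params(1, 10, 0, sigma_m = 1)
  tr0 <- simulate_vpd(d, seg, 21)
  m0 <- tapply(tr0$normalized_error_deg, tr0$disparity_deg, mean)
  expect_lt(abs(sum(m0 * lv) / sum(lv^2)), 0.1)
})

test_that("single-trial limits follow the model", {
  # p_prior = 0, sigma_m = 0: endpoint exactly on target
  seg <- observer_params(2, 5, 0)
  tr <- simulate_reach_trial(15, 40, seg, 3)
  expect_equal(tr$endpoint_deg, 15)
  # visual capture: p_prior = 1, tiny sigma_v -> error ~ -disparity
  cap <- observer_params(1e-3, 10, 1)
  errs <- vapply(1:200, function(s) {
    simulate_reach_trial(0, 40, cap, s)$observed_error_deg
  }, numeric(1))
  expect_equal(mean(errs), -40, tolerance = 0.05)
})

test_that("normalize_errors needs a zero-disparity baseline", {
  df <- data.frame(disparity_deg = c(20, 40), observed_error_deg = c(1, 2))
  expect_error(normalize_errors(df), "0-disparity")
  expect_error(normalize_errors(data.frame(x = 1)), "columns")
  ok <- normalize_errors(data.frame(disparity_deg = c(0, 0, 20),
                                    observed_error_deg = c(1, 3, 5)))
  expect_equal(ok$normalized_error_deg, c(-1, 1, 3))
})

test_that("ratings increase with the common-cause posterior", {
  expect_error(generate_rating(1.2, 1), "p_com")
  r_lo <- generate_rating(rep(0.05, 200), 1)
  r_hi <- generate_rating(rep(0.95, 200), 1)
  expect_true(all(r_lo %in% 1:10) && all(r_hi %in% 1:10))
  expect_gt(mean(r_hi), mean(r_lo) + 5)
})

test_that("residual ownership correlation is positive for a CI observer", {
  p <- observer_params(2, 8, 0.6)
  d <- build_vpd_design(4)
  tr <- simulate_vpd(d, p, 31, rating_noise_sd = 0.5)
  res <- residual_ownership_correlation(tr)
  expect_false(res$degenerate)
  expect_gt(res$n, 10)
  expect_gt(res$r, 0)
})

test_that("degenerate ratings are flagged, not crashed on", {
  tr <- data.frame(disparity_deg = rep(c(-20, 20), each = 5),
                   normalized_error_deg = rnorm(10),
                   rating = rep(7L, 10))
  res <- residual_ownership_correlation(tr)
  expect_true(res$degenerate)
  expect_true(is.na(res$r))
  expect_error(residual_ownership_correlation(
    data.frame(disparity_deg = 1, normalized_error_deg = 1,
               rating = NA_integer_)), "rated")
})
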