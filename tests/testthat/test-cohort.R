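test_that("cohort configuration validates its parameters", {
  cfg <- cohort_config()
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_per_group, 23)
  expect_error(cohort_config(n_per_group = 2), "n_per_group")
  expect_error(cohort_config(sigma_m = -1), "sigma_m")
  expect_error(cohort_config(p_prior_shape = c(0, 2)), "Beta")
  expect_error(cohort_config(pj_link = c(slope = 0.3, intercept = 0.3,
                                         noise_sd = -1, floor = 0.2)),
               "infeasible")
})

# one small cohort shared by the structural tests (fitting is exercised in
# the acceptance suite)
small_cohort <- generate_cohort(cohort_config(n_per_group = 4, seed = 7))

test_that("the generated cohort has the full per-participant structure", {
  p <- small_cohort$participants
  expect_equal(nrow(p), 8)
  expect_equal(as.vector(table(p$group)[c("HO", "HY")]), c(4L, 4L))
  expect_true(all(p$sigma_p_true > 0 & p$sigma_v_true > 0))
  expect_true(all(p$p_prior_true >= 0 & p$p_prior_true <= 1))
  expect_true(all(is.finite(p$sigma_pj) & is.finite(p$sigma_ol) &
                    is.finite(p$sigma_mj)))
  expect_true(all(p$tpd_hand_cm > 0 & p$tpd_forearm_cm > 0))
  expect_equal(nrow(small_cohort$trials), 8 * 123)
  expect_equal(mean(p$ed_arm_length[p$group == "HO"] <
                      p$ed_arm_length[p$group == "HY"]), 1,
               tolerance = 0.5) # direction holds on average, not per pair
})

test_that("cohort generation is reproducible and seed-sensitive", {
  again <- generate_cohort(cohort_config(n_per_group = 4, seed = 7))
  expect_identical(small_cohort$participants, again$participants)
  other <- generate_cohort(cohort_config(n_per_group = 4, seed = 8))
  expect_false(identical(small_cohort$participants$sigma_p_true,
                         other$participants$sigma_p_true))
})

test_that("landmarks reproduce the generated dimension indices exactly", {
  p <- small_cohort$participants
  lm <- small_cohort$landmarks
  for (pid in p$participant_id[c(1, 5)]) {
    build <- function(fl) {
      sub <- lm[lm$participant_id == pid & lm$flavor == fl, ]
      pts <- lapply(c("index_tip", "ring_tip", "internal_wrist",
                      "external_wrist", "elbow"), function(nm) {
        as.numeric(sub[sub$landmark == nm, c("x_cm", "y_cm")])
      })
      landmark_set(pts[[1]], pts[[2]], pts[[3]], pts[[4]], pts[[5]],
                   flavor = fl)
    }
    idx <- dimension_indices(build("real"), build("perceived"))
    expect_equal(idx$ed[idx$body_part == "arm_length"],
                 p$ed_arm_length[p$participant_id == pid], tolerance = 1e-8)
  }
})

test_that("the predictor table holds the HO regression design", {
  tab <- build_predictor_table(small_cohort)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("arm_tactile_2pd", "hand_tactile_2pd", "sigma_pj",
                    "sigma_ol", "sigma_mj", "digit_span_forward",
                    "digit_span_backward", "tmt_b_minus_a",
                    "ee_arm_length") %in% names(tab)))
  expect_true(all(startsWith(tab$participant_id, "HO")))
})

test_that("backward digit span is near-constant by construction", {
  tab <- build_predictor_table(
    generate_cohort(cohort_config(n_per_group = 12, seed = 3)))
  v <- tab$digit_span_backward
  expect_lte(length(v) - max(table(v)), 1)
  expect_true("digit_span_backward" %in% screen_predictors(tab)$excluded)
})

test_that("export writes the documented files and a valid trials schema", {
  dir <- withr::local_tempdir()
  man <- export_cohort(small_cohort, dir)
  for (f in c("trials.csv", "unisensory.csv", "landmarks.csv",
              "predictors.csv", "participants.csv", "manifest.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  rep <- validate_trials_file(file.path(dir, "trials.csv"))
  expect_true(rep$valid)
  expect_equal(man$seed, 7)
  tr <- utils::read.csv(file.path(dir, "trials.csv"))
  expect_false("p_com" %in% names(tr)) # latent truth is not exported
})

test_that("group structure points the right way at generator defaults", {
  cfg <- cohort_config(n_per_group = 12, seed = 42)
  co <- generate_cohort(cfg)
  p <- co$participants
  ho <- p$group == "HO"
  expect_gt(mean(p$sigma_p_true[ho]), mean(p$sigma_p_true[!ho]))
  expect_gt(mean(p$tpd_hand_cm[ho]), mean(p$tpd_hand_cm[!ho]))
  expect_lt(mean(p$ed_arm_length[ho]), mean(p$ed_arm_length[!ho]))
  # priors share a distribution across groups
  expect_gt(suppressWarnings(
    stats::wilcox.test(p$p_prior_true[ho], p$p_prior_true[!ho])$p.value), 0.05)
})
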