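# Synthetic two-group cohort generator: healthy older (HO) and healthy
# younger (HY) observers with the statistical structure the pipeline is meant
# to detect -- higher proprioceptive noise in HO, equal common-cause priors,
# arm-length underestimation in HO, and a linear dependence of arm-length
# misperception on cognitive flexibility, midline variability and open-loop
# variability.

#' Configuration of the synthetic cohort
#'
#' Distributions are parameterized per group, HO first. Sensory noises are
#' lognormal (median, log-SD), the common-cause prior is Beta and identical
#' across groups by default, and the judgment-task observer SD is tied to the
#' proprioceptive noise by a linear linkage with Gaussian scatter. Arm-length
#' misperception in the HO group follows a linear model on the measured
#' cognitive-flexibility z score and the measured midline/open-loop
#' variabilities.
#'
#' @param n_per_group Participants per group (default 23).
#' @param sigma_p_median,sigma_p_sdlog Proprioceptive noise medians (deg,
#'   `c(HO, HY)`) and common log-SD.
#' @param sigma_v_median,sigma_v_sdlog Visual noise medians and log-SD.
#' @param p_prior_shape Beta shape parameters of the common-cause prior (both
#'   groups).
#' @param sigma_m Motor noise SD, degrees (both groups).
#' @param pj_link `c(slope, intercept, noise_sd, floor)` mapping `sigma_p` to
#'   the judgment-task observer SD (deg).
#' @param ol_median,ol_sdlog,mj_median,mj_sdlog Open-loop and midline observer
#'   SD distributions (equal across groups: those tasks showed no age
#'   difference).
#' @param tpd_hand_median,tpd_forearm_median Two-point thresholds, cm,
#'   `c(HO, HY)`.
#' @param tpd_sdlog,tpd_lapse Threshold log-SD and response lapse rate.
#' @param arm_ed_anchor Mean arm-length estimated dimension, `c(HO, HY)`.
#' @param ee_betas Coefficients `c(tmt, sigma_mj, sigma_ol)` of the HO
#'   arm-length error model (applied to the measured scores).
#' @param ee_scale Overall scaling of the linear signal (keeps EE within its
#'   natural range).
#' @param ee_noise_sd Residual SD of the EE model.
#' @param rating_noise_sd Jitter of the synthetic ownership ratings.
#' @param seed Master seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 23,
                          sigma_p_median = c(9, 5), sigma_p_sdlog = 0.35,
                          sigma_v_median = c(4, 3), sigma_v_sdlog = 0.30,
                          p_prior_shape = c(4, 2),
                          sigma_m = 2,
                          pj_link = c(slope = 0.30, intercept = 0.30,
                                      noise_sd = 0.30, floor = 0.20),
                          ol_median = 5, ol_sdlog = 0.30,
                          mj_median = 4, mj_sdlog = 0.25,
                          tpd_hand_median = c(0.7, 0.4),
                          tpd_forearm_median = c(3.0, 2.5),
                          tpd_sdlog = 0.25, tpd_lapse = 0.02,
                          arm_ed_anchor = c(0.88, 0.97),
                          ee_betas = c(tmt = 0.10, sigma_mj = 0.09,
                                       sigma_ol = 0.02),
                          ee_scale = 0.5,
                          ee_noise_sd = 0.072,
                          rating_noise_sd = 1,
                          seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_per_group < 3) stop("`n_per_group` must be >= 3", call. = FALSE)
  pos <- c(cfg$sigma_p_median, cfg$sigma_p_sdlog, cfg$sigma_v_median,
           cfg$sigma_v_sdlog, cfg$ol_median, cfg$ol_sdlog, cfg$mj_median,
           cfg$mj_sdlog, cfg$tpd_hand_median, cfg$tpd_forearm_median,
           cfg$tpd_sdlog, cfg$ee_noise_sd, cfg$rating_noise_sd)
  if (any(pos <= 0)) stop("all scale parameters must be > 0", call. = FALSE)
  if (cfg$sigma_m < 0) stop("`sigma_m` must be >= 0", call. = FALSE)
  if (cfg$pj_link[["noise_sd"]] < 0 || cfg$pj_link[["floor"]] <= 0) {
    stop("infeasible proprioceptive linkage", call. = FALSE)
  }
  if (any(cfg$p_prior_shape <= 0)) stop("Beta shapes must be > 0", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

# geometric template realizing exact limb dimensions; elbow at origin,
# limb along +y; a rigid motion is applied afterwards for realism
landmarks_from_dims <- function(arm_len, arm_w, hand_len, hand_w,
                                flavor, angle = 0, shift = c(0, 0)) {
  wy <- sqrt(arm_len^2 - (arm_w / 2)^2)
  fy <- wy + sqrt(hand_len^2 - ((arm_w - hand_w) / 2)^2)
  pts <- rbind(
    index_tip = c(-hand_w / 2, fy),
    ring_tip = c(hand_w / 2, fy),
    internal_wrist = c(-arm_w / 2, wy),
    external_wrist = c(arm_w / 2, wy),
    elbow = c(0, 0)
  )
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  pts <- sweep(pts %*% t(rot), 2, shift, "+")
  landmark_set(pts[1, ], pts[2, ], pts[3, ], pts[4, ], pts[5, ],
               flavor = flavor)
}

#' Generate a complete synthetic cohort
#'
#' Draws per-participant observer parameters from the group distributions,
#' simulates the full three-block VPD session (with ownership ratings), runs
#' the judgment, open-loop, midline and two-point protocols with parameters
#' linked to the generative proprioceptive noise, draws cognitive scores, and
#' constructs real and perceived body landmarks whose arm-length error follows
#' the configured linear model (HO group).
#'
#' @param config A [cohort_config()].
#' @return A list of class `vpd_cohort` with elements `participants` (one row
#'   per participant), `trials` (all VPD trials), `landmarks` (long-format
#'   coordinates) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$seed
  n <- config$n_per_group
  groups <- c("HO", "HY")

  part_rows <- list(); trial_rows <- list(); lm_rows <- list()
  idx <- 0L
  for (g in seq_along(groups)) {
    grp <- groups[g]
    draws <- with_seed(derive_seed(seed, 1000L + g), {
      list(
        sigma_p = exp(log(config$sigma_p_median[g]) +
                        config$sigma_p_sdlog * stats::rnorm(n)),
        sigma_v = exp(log(config$sigma_v_median[g]) +
                        config$sigma_v_sdlog * stats::rnorm(n)),
        p_prior = stats::rbeta(n, config$p_prior_shape[1],
                               config$p_prior_shape[2]),
        pj_eps = stats::rnorm(n), pj_bias = 0.5 * stats::rnorm(n),
        ol_sd = exp(log(config$ol_median) + config$ol_sdlog * stats::rnorm(n)),
        ol_bias = stats::rnorm(n),
        mj_sd = exp(log(config$mj_median) + config$mj_sdlog * stats::rnorm(n)),
        mj_bias = 2 * stats::rnorm(n),
        tpd_hand = exp(log(config$tpd_hand_median[g]) +
                         config$tpd_sdlog * stats::rnorm(n)),
        tpd_forearm = exp(log(config$tpd_forearm_median[g]) +
                            config$tpd_sdlog * stats::rnorm(n)),
        dsf = pmin(9, pmax(3, round(stats::rnorm(n, c(5.5, 6.3)[g], 1)))),
        tmt_raw = pmax(5, stats::rnorm(n, c(60, 35)[g], c(22, 12)[g])),
        population = sample(c("ita", "fra"), n, TRUE, prob = c(0.2, 0.8)),
        scale_f = 1 + 0.06 * stats::rnorm(n),
        ed_other = matrix(1 + 0.05 * stats::rnorm(3 * n), ncol = 3),
        ed_arm_hy = stats::rnorm(n, config$arm_ed_anchor[2], 0.045),
        ee_eps = stats::rnorm(n, 0, config$ee_noise_sd),
        lm_angle = stats::runif(n, -0.17, 0.17),
        lm_shift = matrix(stats::runif(2 * n, -5, 5), ncol = 2)
      )
    })
    # backward digit span: near-constant (all but one participant identical)
    dsb <- rep(4L, n)
    dsb[with_seed(derive_seed(seed, 1100L + g), sample.int(n, 1))] <- 3L

    pj_sd <- pmax(config$pj_link[["floor"]],
                  config$pj_link[["slope"]] * draws$sigma_p +
                    config$pj_link[["intercept"]] +
                    config$pj_link[["noise_sd"]] * draws$pj_eps)

    for (i in seq_len(n)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", grp, i)
      params <- observer_params(draws$sigma_v[i], draws$sigma_p[i],
                                draws$p_prior[i], config$sigma_m)
      des <- build_vpd_design(derive_seed(seed, 2000L + idx))
      tr <- simulate_vpd(des, params, derive_seed(seed, 3000L + idx),
                         rating_noise_sd = config$rating_noise_sd)
      tr <- cbind(participant_id = pid, group = grp, tr)
      trial_rows[[idx]] <- tr

      pj <- pj_protocol(list(bias = draws$pj_bias[i], sd = pj_sd[i]),
                        derive_seed(seed, 4000L + idx))
      ol <- ol_protocol(list(bias = draws$ol_bias[i], sd = draws$ol_sd[i]),
                        derive_seed(seed, 5000L + idx))
      mj <- mj_protocol(list(bias = draws$mj_bias[i], sd = draws$mj_sd[i]),
                        derive_seed(seed, 6000L + idx))
      th <- tpd_staircase(draws$tpd_hand[i], "hand",
                          derive_seed(seed, 7000L + idx),
                          lapse = config$tpd_lapse)
      tf <- tpd_staircase(draws$tpd_forearm[i], "forearm",
                          derive_seed(seed, 8000L + idx),
                          lapse = config$tpd_lapse)

      part_rows[[idx]] <- data.frame(
        participant_id = pid, group = grp,
        population = draws$population[i],
        sigma_v_true = draws$sigma_v[i], sigma_p_true = draws$sigma_p[i],
        p_prior_true = draws$p_prior[i], sigma_m_true = config$sigma_m,
        pj_observer_sd = pj_sd[i],
        sigma_pj = pj$sigma_pj, sigma_ol = ol$sigma_ol, sigma_mj = mj$sigma_mj,
        tpd_hand_cm = th$threshold, tpd_forearm_cm = tf$threshold,
        digit_span_forward = draws$dsf[i], digit_span_backward = dsb[i],
        tmt_raw_s = draws$tmt_raw[i]
      )
    }
  }
  participants <- do.call(rbind, part_rows)
  trials <- do.call(rbind, trial_rows)

  # cognitive-flexibility normalization: within population, then pooled
  participants$tmt_b_minus_a <- normalize_across_populations(
    participants$tmt_raw_s, participants$population)

  # arm-length estimated dimension: HO follows the linear misperception
  # model on the *measured* scores; HY scatters around its anchor
  ho <- participants$group == "HO"
  b <- config$ee_betas
  signal <- config$ee_scale *
    (b[["tmt"]] * participants$tmt_b_minus_a[ho] +
       b[["sigma_mj"]] * (participants$sigma_mj[ho] -
                            mean(participants$sigma_mj[ho])) +
       b[["sigma_ol"]] * (participants$sigma_ol[ho] -
                            mean(participants$sigma_ol[ho])))
  ee_ho <- pmax(0.01, (1 - config$arm_ed_anchor[1]) + signal +
                  c(with_seed(derive_seed(seed, 9000L),
                              stats::rnorm(sum(ho), 0, config$ee_noise_sd))))
  participants$ed_arm_length <- NA_real_
  participants$ed_arm_length[ho] <- 1 - ee_ho
  hy_draw <- with_seed(derive_seed(seed, 9001L),
                       stats::rnorm(sum(!ho), config$arm_ed_anchor[2], 0.045))
  participants$ed_arm_length[!ho] <- hy_draw
  participants$ee_arm_length <- abs(participants$ed_arm_length - 1)

  # landmark coordinates realizing the drawn dimensions exactly
  base <- c(arm_len = 25.5, arm_w = 6.2, hand_len = 18.5, hand_w = 4.5)
  participants$real_arm_length <- NA_real_
  lm_list <- list()
  aux <- with_seed(derive_seed(seed, 9500L), {
    list(scale_f = 1 + 0.06 * stats::rnorm(nrow(participants)),
         ed_other = matrix(1 + 0.05 * stats::rnorm(3 * nrow(participants)),
                           ncol = 3),
         angle = stats::runif(nrow(participants), -0.17, 0.17),
         shift = matrix(stats::runif(2 * nrow(participants), -5, 5), ncol = 2))
  })
  for (j in seq_len(nrow(participants))) {
    f <- aux$scale_f[j]
    real_dims <- base * f
    per_dims <- c(arm_len = unname(real_dims["arm_len"]) *
                    participants$ed_arm_length[j],
                  arm_w = unname(real_dims["arm_w"]) * aux$ed_other[j, 1],
                  hand_len = unname(real_dims["hand_len"]) * aux$ed_other[j, 2],
                  hand_w = unname(real_dims["hand_w"]) * aux$ed_other[j, 3])
    real <- landmarks_from_dims(real_dims["arm_len"], real_dims["arm_w"],
                                real_dims["hand_len"], real_dims["hand_w"],
                                "real", aux$angle[j], aux$shift[j, ])
    perc <- landmarks_from_dims(per_dims["arm_len"], per_dims["arm_w"],
                                per_dims["hand_len"], per_dims["hand_w"],
                                "perceived", aux$angle[j], aux$shift[j, ])
    participants$real_arm_length[j] <- unname(limb_dimensions(real)["arm_length"])
    for (set in list(real, perc)) {
      lm_list[[length(lm_list) + 1L]] <- data.frame(
        participant_id = participants$participant_id[j],
        flavor = attr(set, "flavor"),
        landmark = rownames(set),
        x_cm = set[, "x_cm"], y_cm = set[, "y_cm"], row.names = NULL)
    }
  }
  landmarks <- do.call(rbind, lm_list)

  structure(list(participants = participants, trials = trials,
                 landmarks = landmarks, config = config),
            class = "vpd_cohort")
}

#' Predictor table for the arm-length error regression
#'
#' Extracts the regression design used for the HO group: tactile thresholds,
#' the three proprioceptive/alignment variabilities, the two memory spans, the
#' normalized cognitive-flexibility score and the arm-length estimated error
#' as response.
#'
#' @param cohort A `vpd_cohort` object.
#' @return Data frame with `participant_id`, the predictor columns and
#'   `ee_arm_length`.
#' @export
build_predictor_table <- function(cohort) {
  stopifnot(inherits(cohort, "vpd_cohort"))
  p <- cohort$participants
  p <- p[p$group == "HO", ]
  data.frame(
    participant_id = p$participant_id,
    arm_tactile_2pd = p$tpd_forearm_cm,
    hand_tactile_2pd = p$tpd_hand_cm,
    sigma_pj = p$sigma_pj,
    sigma_ol = p$sigma_ol,
    sigma_mj = p$sigma_mj,
    digit_span_forward = p$digit_span_forward,
    digit_span_backward = p$digit_span_backward,
    tmt_b_minus_a = p$tmt_b_minus_a,
    ee_arm_length = p$ee_arm_length
  )
}

#' Fit the causal-inference model to every cohort participant
#'
#' @param cohort A `vpd_cohort`.
#' @param n_sim,n_starts,maxit Fitting settings (see [fit_participant()]).
#' @param seed Integer seed for the fits.
#' @param sigma_m Motor noise assumed during fitting; defaults to the
#'   generator's value.
#' @return The participants table with `sigma_v_hat`, `sigma_p_hat`,
#'   `p_prior_hat`, `loglik`, `converged` columns appended.
#' @export
fit_cohort <- function(cohort, n_sim = 3000, n_starts = 3, seed = 1,
                       sigma_m = cohort$config$sigma_m, maxit = 200) {
  stopifnot(inherits(cohort, "vpd_cohort"))
  ids <- cohort$participants$participant_id
  fits <- lapply(seq_along(ids), function(i) {
    tr <- cohort$trials[cohort$trials$participant_id == ids[i], ]
    fit_participant(tr, n_starts = n_starts, n_sim = n_sim,
                    seed = derive_seed(seed, i), sigma_m = sigma_m,
                    maxit = maxit, pool = 24)
  })
  cbind(cohort$participants,
        do.call(rbind, fits)[, c("sigma_v_hat", "sigma_p_hat", "p_prior_hat",
                                 "loglik", "converged")])
}

#' Headline group statistics of a fitted cohort
#'
#' The synthetic mirror of the study's main dissociation: a one-sided rank
#' test for higher fitted proprioceptive noise in the HO group, a two-sided
#' rank test for a common-cause prior difference (none is expected under the
#' generator), the pooled Spearman correlation between fitted proprioceptive
#' noise and the judgment-task variability, and the group means of the
#' arm-length estimated dimension.
#'
#' @param fitted Output of [fit_cohort()].
#' @return A list with `p_sigma_p_ho_greater`, `p_p_prior_diff`,
#'   `spearman_sigma_p_pj`, `ed_arm_means`.
#' @export
cohort_summary <- function(fitted) {
  ho <- fitted$group == "HO"
  list(
    p_sigma_p_ho_greater = suppressWarnings(
      stats::wilcox.test(fitted$sigma_p_hat[ho], fitted$sigma_p_hat[!ho],
                         alternative = "greater")$p.value),
    p_p_prior_diff = suppressWarnings(
      stats::wilcox.test(fitted$p_prior_hat[ho],
                         fitted$p_prior_hat[!ho])$p.value),
    spearman_sigma_p_pj = stats::cor(fitted$sigma_p_hat, fitted$sigma_pj,
                                     method = "spearman"),
    ed_arm_means = tapply(fitted$ed_arm_length, fitted$group, mean)
  )
}
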