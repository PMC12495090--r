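# VPD task: design construction, trial simulation under the causal-inference
# observer, error normalization, synthetic ownership ratings, and the
# residual implicit/explicit ownership statistic.

vpd_targets_12 <- c(-45, -30, -15, 0, 15, 30, 45)
vpd_disparities_12 <- c(-40, -26.6, -13.3, 0, 13.3, 26.6, 40)
vpd_disparities_3 <- c(-40, -20, 0, 20, 40)
vpd_all_disparities <- sort(unique(c(vpd_disparities_12, vpd_disparities_3)))

#' Build the three-block VPD task design
#'
#' Blocks 1 and 2 each cross 7 targets (0, +/-15, +/-30, +/-45 degrees from
#' midline) with 7 disparities (0, +/-13.3, +/-26.6, +/-40 degrees), 49 trials
#' per block. Block 3 crosses a 5-target subset with 5 disparities
#' (0, +/-20, +/-40 degrees) and collects an ownership rating on every trial.
#' Trial order is randomized independently within each block.
#'
#' @param seed Integer seed controlling trial order.
#' @param block3_targets The 5 targets used in the rating block. The task
#'   defines 5 of the 7 targets without naming them; the default keeps the
#'   central five (0, +/-15, +/-30 degrees).
#' @return A data frame of class `vpd_design` with columns `block`,
#'   `trial_index`, `target_deg`, `disparity_deg`, `collect_rating`.
#' @export
build_vpd_design <- function(seed, block3_targets = c(-30, -15, 0, 15, 30)) {
  if (length(block3_targets) != 5 || !all(block3_targets %in% vpd_targets_12)) {
    stop("`block3_targets` must be 5 of the 7 task targets", call. = FALSE)
  }
  one_block <- function(block, targets, disparities, rating, stream) {
    g <- expand.grid(target_deg = targets, disparity_deg = disparities)
    g <- g[with_seed(derive_seed(seed, stream), sample.int(nrow(g))), ]
    data.frame(block = block, trial_index = seq_len(nrow(g)),
               target_deg = g$target_deg, disparity_deg = g$disparity_deg,
               collect_rating = rating, row.names = NULL)
  }
  out <- rbind(
    one_block(1L, vpd_targets_12, vpd_disparities_12, FALSE, 1L),
    one_block(2L, vpd_targets_12, vpd_disparities_12, FALSE, 2L),
    one_block(3L, block3_targets, vpd_disparities_3, TRUE, 3L)
  )
  class(out) <- c("vpd_design", class(out))
  out
}

# Core vectorized reach simulation. The proprioceptive reference is the
# pre-movement hand position (taken as 0; the model is translation invariant
# in angle), the virtual hand sits at `disparity` from it. The estimation bias
# toward the virtual hand displaces the endpoint opposite the disparity:
# endpoint = target - (s_hat_p - x_p) + motor noise.
simulate_reach_errors <- function(disparity, params, z_v, z_p, z_m) {
  x_v <- disparity + params$sigma_v * z_v
  x_p <- params$sigma_p * z_p
  p_com <- pcom_closed_form(x_v, x_p, params$sigma_v, params$sigma_p,
                            params$p_prior)
  w_v <- params$sigma_p^2 / (params$sigma_v^2 + params$sigma_p^2)
  x_ff <- w_v * x_v + (1 - w_v) * x_p
  s_hat <- p_com * x_ff + (1 - p_com) * x_p
  list(observed_error = -(s_hat - x_p) + params$sigma_m * z_m, p_com = p_com)
}

#' Simulate one VPD reaching trial
#'
#' Samples sensory representations at the pre-movement hand position with the
#' trial's disparity, forms the causal-inference position estimate, and
#' displaces the reach endpoint by the estimation bias (plus motor noise).
#' Pure proprioceptive guidance (`p_prior = 0`, `sigma_m = 0`) gives zero
#' expected error; full visual capture (`p_prior = 1`, `sigma_v -> 0`) gives an
#' expected error of minus the disparity.
#'
#' @param target Target angle, degrees.
#' @param disparity Visuo-proprioceptive disparity, degrees (positive =
#'   clockwise rotation of the virtual hand).
#' @param params An [observer_params()] object.
#' @param seed Integer seed.
#' @param block,trial_index Optional bookkeeping fields copied to the output.
#' @return A one-row data frame with `block`, `trial_index`, `target_deg`,
#'   `disparity_deg`, `endpoint_deg`, `observed_error_deg`, `p_com`.
#' @export
simulate_reach_trial <- function(target, disparity, params, seed,
                                 block = NA_integer_, trial_index = NA_integer_) {
  stopifnot(inherits(params, "observer_params"))
  with_seed(seed, {
    z <- stats::rnorm(3)
    r <- simulate_reach_errors(disparity, params, z[1], z[2], z[3])
    data.frame(block = block, trial_index = trial_index,
               target_deg = target, disparity_deg = disparity,
               endpoint_deg = target + r$observed_error,
               observed_error_deg = r$observed_error,
               p_com = r$p_com)
  })
}

#' Simulate a full VPD session for one observer
#'
#' Runs every trial of a [build_vpd_design()] design under the causal-inference
#' observer, then normalizes errors against the 0-disparity baseline and, on
#' rating trials, converts the trial's common-cause posterior into a 1-10
#' ownership rating via [generate_rating()].
#'
#' @param design A `vpd_design` data frame.
#' @param params An [observer_params()] object.
#' @param seed Integer seed.
#' @param rating_noise_sd SD of the Gaussian jitter on the latent rating
#'   (default 1).
#' @return A data frame of trials with `normalized_error_deg` and `rating`
#'   (NA outside block 3).
#' @export
simulate_vpd <- function(design, params, seed, rating_noise_sd = 1) {
  stopifnot(inherits(design, "vpd_design"), inherits(params, "observer_params"))
  n <- nrow(design)
  with_seed(derive_seed(seed, 10L), {
    z <- matrix(stats::rnorm(3 * n), ncol = 3)
    r <- simulate_reach_errors(design$disparity_deg, params,
                               z[, 1], z[, 2], z[, 3])
    out <- data.frame(
      block = design$block, trial_index = design$trial_index,
      target_deg = design$target_deg, disparity_deg = design$disparity_deg,
      endpoint_deg = design$target_deg + r$observed_error,
      observed_error_deg = r$observed_error,
      p_com = r$p_com
    )
    out$rating <- NA_integer_
    idx <- which(design$collect_rating)
    if (length(idx)) {
      eps <- rating_noise_sd * stats::rnorm(length(idx))
      out$rating[idx] <- as.integer(
        pmin(10, pmax(1, round_half_up(1 + 9 * r$p_com[idx] + eps))))
    }
    normalize_errors(out)
  })
}

#' Normalize reaching errors against the 0-disparity baseline
#'
#' Removes systematic reaching bias by subtracting from every observed error
#' the mean observed error over all 0-disparity trials; after normalization the
#' mean normalized error at 0 disparity is exactly 0.
#'
#' @param trials Data frame with columns `disparity_deg` and
#'   `observed_error_deg`.
#' @return The input with a `normalized_error_deg` column added/replaced.
#' @export
normalize_errors <- function(trials) {
  if (!all(c("disparity_deg", "observed_error_deg") %in% names(trials))) {
    stop("`trials` must have `disparity_deg` and `observed_error_deg` columns",
         call. = FALSE)
  }
  at0 <- trials$disparity_deg == 0
  if (!any(at0)) {
    stop("no 0-disparity trials: baseline for normalization is missing",
         call. = FALSE)
  }
  trials$normalized_error_deg <-
    trials$observed_error_deg - mean(trials$observed_error_deg[at0])
  trials
}

#' Map a common-cause posterior to a 1-10 ownership rating
#'
#' Synthetic-data device only (never used in fitting): the latent rating is
#' `1 + 9 * p_com` plus Gaussian jitter, rounded half-up and clipped to
#' `[1, 10]`. Monotone in `p_com` in expectation.
#'
#' @param p_com Posterior probability of common cause, in `[0, 1]`.
#' @param seed Integer seed.
#' @param noise_sd Jitter SD (default 1).
#' @return Integer rating(s) in `[1, 10]`.
#' @export
generate_rating <- function(p_com, seed, noise_sd = 1) {
  if (any(p_com < 0 | p_com > 1)) stop("`p_com` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    eps <- noise_sd * stats::rnorm(length(p_com))
    as.integer(pmin(10, pmax(1, round_half_up(1 + 9 * p_com + eps))))
  })
}

#' Trial-level correlation of residual ownership and residual reaching error
#'
#' Within the rating block, subtracts from each rating the mean rating at the
#' same disparity, and from each normalized error its disparity-level mean;
#' residual errors are converted to residual *attraction* (minus the residual
#' error times the sign of the disparity) so that a stronger pull toward the
#' virtual hand maps to a positive residual. Zero-disparity trials carry no
#' information and are excluded. Returns the Pearson correlation over the
#' remaining trials: positive when trials felt as more "owned" also show more
#' visual attraction.
#'
#' @param trials Data frame with `disparity_deg`, `normalized_error_deg`,
#'   `rating` (block-3 trials of [simulate_vpd()]).
#' @return A list with `r` (Pearson correlation, `NA` if degenerate), `n`
#'   (trials used) and `degenerate` (TRUE when residual ratings have zero
#'   variance and the statistic is undefined).
#' @export
residual_ownership_correlation <- function(trials) {
  t3 <- trials[!is.na(trials$rating), , drop = FALSE]
  if (!nrow(t3)) stop("no rated trials supplied", call. = FALSE)
  t3 <- t3[t3$disparity_deg != 0, , drop = FALSE]
  if (length(unique(t3$disparity_deg)) < 2) {
    stop("need at least two nonzero-disparity levels", call. = FALSE)
  }
  res_rating <- t3$rating -
    stats::ave(as.numeric(t3$rating), t3$disparity_deg)
  res_error <- -(t3$normalized_error_deg -
                   stats::ave(t3$normalized_error_deg, t3$disparity_deg)) *
    sign(t3$disparity_deg)
  if (stats::sd(res_rating) < 1e-12 || stats::sd(res_error) < 1e-12) {
    return(list(r = NA_real_, n = nrow(t3), degenerate = TRUE))
  }
  list(r = stats::cor(res_error, res_rating), n = nrow(t3), degenerate = FALSE)
}
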