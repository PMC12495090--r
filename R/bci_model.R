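#' Observer parameters for the causal-inference model
#'
#' Bundles the generative parameters of a single observer: the standard
#' deviations of the Gaussian noise corrupting the visual and proprioceptive
#' encodings of hand position, the prior probability that both signals share a
#' common cause (i.e. that the seen hand is one's own), and an optional
#' motor-execution noise added to reach endpoints.
#'
#' @param sigma_v Visual noise SD, degrees. Must be positive.
#' @param sigma_p Proprioceptive noise SD, degrees. Must be positive.
#' @param p_prior Prior probability of a common cause, in `[0, 1]`.
#' @param sigma_m Motor-execution noise SD, degrees (`>= 0`). The inference
#'   equations stop at the position estimate; `sigma_m` lets simulated reach
#'   endpoints carry execution noise that is not sensory in origin, so that
#'   fitted variability is not forced into `sigma_v`/`sigma_p`. Default 0.
#'
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(sigma_v = 3, sigma_p = 8, p_prior = 0.6)
#' @export
observer_params <- function(sigma_v, sigma_p, p_prior, sigma_m = 0) {
  stopifnot_scalar(sigma_v, "sigma_v")
  stopifnot_scalar(sigma_p, "sigma_p")
  stopifnot_scalar(p_prior, "p_prior")
  stopifnot_scalar(sigma_m, "sigma_m")
  if (sigma_v <= 0) stop("`sigma_v` must be > 0", call. = FALSE)
  if (sigma_p <= 0) stop("`sigma_p` must be > 0", call. = FALSE)
  if (p_prior < 0 || p_prior > 1) stop("`p_prior` must be in [0, 1]", call. = FALSE)
  if (sigma_m < 0) stop("`sigma_m` must be >= 0", call. = FALSE)
  structure(
    list(sigma_v = sigma_v, sigma_p = sigma_p,
         p_prior = p_prior, sigma_m = sigma_m),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "observer_params: sigma_v = %.3g deg, sigma_p = %.3g deg, p_prior = %.3g, sigma_m = %.3g deg\n",
    x$sigma_v, x$sigma_p, x$p_prior, x$sigma_m))
  invisible(x)
}

#' Trial stimulus: true hand and virtual-hand angles
#'
#' Angles are measured in degrees from the shoulder; positive disparities
#' correspond to a clockwise rotation of the virtual hand relative to the real
#' one.
#'
#' @param s_p True (real-hand) angle, degrees, in `[-90, 90]`.
#' @param s_v Virtual-hand angle, degrees, in `[-90, 90]`.
#' @return An object of class `trial_stimulus` with fields `s_p`, `s_v`,
#'   `disparity` (`s_v - s_p`).
#' @export
trial_stimulus <- function(s_p, s_v) {
  stopifnot_scalar(s_p, "s_p")
  stopifnot_scalar(s_v, "s_v")
  if (abs(s_p) > 90 || abs(s_v) > 90) {
    stop("stimulus angles must lie in [-90, 90] degrees", call. = FALSE)
  }
  structure(list(s_p = s_p, s_v = s_v, disparity = s_v - s_p),
            class = "trial_stimulus")
}

#' Reliability-based fusion weights
#'
#' Cue weights proportional to reliability (inverse variance):
#' `w_v = r_v / (r_v + r_p)` with `r_i = 1 / sigma_i^2`. The weights sum to 1.
#'
#' @param sigma_v,sigma_p Cue noise SDs in degrees, both `> 0`.
#' @return A list of class `fusion_weights` with `w_v`, `w_p`, `r_v`, `r_p`.
#' @examples
#' fusion_weights(1, 2) # visual weight 0.8
#' @export
fusion_weights <- function(sigma_v, sigma_p) {
  stopifnot_scalar(sigma_v, "sigma_v")
  stopifnot_scalar(sigma_p, "sigma_p")
  if (sigma_v <= 0 || sigma_p <= 0) {
    stop("`sigma_v` and `sigma_p` must be > 0", call. = FALSE)
  }
  r_v <- 1 / sigma_v^2
  r_p <- 1 / sigma_p^2
  structure(list(w_v = r_v / (r_v + r_p), w_p = r_p / (r_v + r_p),
                 r_v = r_v, r_p = r_p),
            class = "fusion_weights")
}

#' Forced-fusion estimate of hand position
#'
#' The reliability-weighted average of the noisy visual and proprioceptive
#' position samples, i.e. the optimal estimate under mandatory integration.
#' Always lies between `x_v` and `x_p`.
#'
#' @param x_v,x_p Noisy visual / proprioceptive position samples, degrees.
#'   May be vectors of equal length.
#' @param sigma_v,sigma_p Cue noise SDs, degrees, `> 0`.
#' @return Numeric vector of fused position estimates, degrees.
#' @export
forced_fusion_estimate <- function(x_v, x_p, sigma_v, sigma_p) {
  w <- fusion_weights(sigma_v, sigma_p)
  w$w_v * x_v + w$w_p * x_p
}

# Vectorized common-cause posterior, log-space for numerical stability.
# L(C=1) = (1/alpha) exp(-delta^2 / (2 sigma_s^2)), alpha = 180 sqrt(2 pi sigma_s^2)
# L(C=2) = 1/180^2
pcom_closed_form <- function(x_v, x_p, sigma_v, sigma_p, p_prior) {
  sigma_s2 <- sigma_v^2 + sigma_p^2
  if (p_prior <= 0) return(rep(0, length(x_v)))
  if (p_prior >= 1) return(rep(1, length(x_v)))
  log_l1 <- log(p_prior) - (x_v - x_p)^2 / (2 * sigma_s2) -
    log(180) - 0.5 * log(2 * pi * sigma_s2)
  log_l2 <- log1p(-p_prior) - 2 * log(180)
  1 / (1 + exp(log_l2 - log_l1))
}

#' Posterior probability of a common cause
#'
#' Evaluates the causal-inference posterior that the visual and proprioceptive
#' samples arise from a single hand. The one-cause likelihood is
#' `(1/alpha) * exp(-delta_s^2 / (2 * sigma_s^2))` with normalization
#' `alpha = 180 * sqrt(2 * pi * (sigma_p^2 + sigma_v^2))` (uniform position
#' prior on the 180-degree reachable range), the two-cause likelihood is
#' `1/180^2`, and the two are mixed by the prior `p_prior`.
#'
#' @param x_v,x_p Noisy sensory samples, degrees (vectors allowed).
#' @param params An [observer_params()] object.
#' @return An object of class `posterior_estimate`: a data frame with columns
#'   `p_com`, `x_ff`, `s_hat_p`, `delta_s`, `sigma_s2`, `alpha`.
#' @examples
#' p <- observer_params(5, 5, 0.5)
#' common_cause_posterior(0, 0, p)$p_com # ~0.910
#' @export
common_cause_posterior <- function(x_v, x_p, params) {
  stopifnot(inherits(params, "observer_params"))
  if (length(x_v) != length(x_p)) {
    stop("`x_v` and `x_p` must have equal length", call. = FALSE)
  }
  sigma_s2 <- params$sigma_v^2 + params$sigma_p^2
  p_com <- pcom_closed_form(x_v, x_p, params$sigma_v, params$sigma_p,
                            params$p_prior)
  x_ff <- forced_fusion_estimate(x_v, x_p, params$sigma_v, params$sigma_p)
  out <- data.frame(
    p_com = p_com,
    x_ff = x_ff,
    s_hat_p = p_com * x_ff + (1 - p_com) * x_p,
    delta_s = abs(x_v - x_p),
    sigma_s2 = sigma_s2,
    alpha = 180 * sqrt(2 * pi * sigma_s2)
  )
  class(out) <- c("posterior_estimate", class(out))
  out
}

#' Final hand-position estimate
#'
#' Model average of the forced-fusion estimate and the pure proprioceptive
#' sample, weighted by the posterior probability of a common cause:
#' `s_hat_p = p_com * x_ff + (1 - p_com) * x_p`. Collapses to `x_p` when
#' `p_com = 0` and to the forced-fusion estimate when `p_com = 1`.
#'
#' @inheritParams common_cause_posterior
#' @return An object of class `posterior_estimate` (see
#'   [common_cause_posterior()]).
#' @export
position_estimate <- function(x_v, x_p, params) {
  common_cause_posterior(x_v, x_p, params)
}

#' Sample noisy sensory representations for one trial
#'
#' Draws `x_v = s_v + N(0, sigma_v)` and `x_p = s_p + N(0, sigma_p)`
#' independently. Samples are not range-clipped: noise may carry them outside
#' the plus/minus 90 degree stimulus range.
#'
#' @param stimulus A [trial_stimulus()] object.
#' @param params An [observer_params()] object.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A list of class `sensory_sample` with `x_v`, `x_p`.
#' @export
sample_sensory <- function(stimulus, params, seed) {
  stopifnot(inherits(stimulus, "trial_stimulus"),
            inherits(params, "observer_params"))
  with_seed(seed, {
    structure(
      list(x_v = stimulus$s_v + params$sigma_v * stats::rnorm(1),
           x_p = stimulus$s_p + params$sigma_p * stats::rnorm(1)),
      class = "sensory_sample"
    )
  })
}
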