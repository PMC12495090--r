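# Unisensory protocols: proprioceptive judgment (PJ) converging staircase,
# open-loop reaching (OL), midline judgment (MJ).

pj_offset_magnitudes <- 30 / 2^(0:4)

#' One proprioceptive-judgment converging staircase
#'
#' Five displayed offsets of fixed, halving magnitude (30, 15, 7.5, 3.75,
#' 1.875 degrees around the target), each mirrored to the side opposite the
#' previous left/right answer. The observer reports "virtual right of real"
#' when the displayed position is at or beyond a per-trial noisy internal hand
#' estimate `N(target + bias, sd)` (ties resolve to "right"). The final
#' estimate is the midpoint of the last displayed position and the 6th
#' position the rule would have shown (magnitude 0.9375 degrees).
#'
#' @param observer_bias Constant bias of the internal hand estimate, degrees.
#' @param observer_sd Trial-to-trial SD of the internal estimate, degrees
#'   (`>= 0`; 0 gives a deterministic observer).
#' @param target Target angle, degrees (offsets are relative to it).
#' @param start_sign `+1` or `-1`: side of the first 30-degree offset.
#' @param seed Integer seed.
#' @return A list of class `staircase_state`: `displayed_offsets` (5 signed
#'   offsets, degrees), `responses` (`"right"`/`"left"`), `final_estimate`
#'   (absolute, degrees) and `final_offset` (relative to the target).
#' @examples
#' # deterministic unbiased observer, start +30: offsets +30 -15 +7.5 -3.75 +1.875
#' pj_staircase(0, 0, target = 0, start_sign = 1, seed = 1)$final_offset # 0.46875
#' @export
pj_staircase <- function(observer_bias, observer_sd, target = 0,
                         start_sign = 1, seed = 1) {
  if (observer_sd < 0) stop("`observer_sd` must be >= 0", call. = FALSE)
  if (!start_sign %in% c(-1, 1)) stop("`start_sign` must be +1 or -1", call. = FALSE)
  with_seed(seed, {
    z <- stats::rnorm(5)
    offsets <- numeric(5)
    responses <- character(5)
    sgn <- start_sign
    for (k in 1:5) {
      offsets[k] <- sgn * pj_offset_magnitudes[k]
      h <- observer_bias + observer_sd * z[k]
      right <- offsets[k] >= h # displayed at/right of internal estimate
      responses[k] <- if (right) "right" else "left"
      sgn <- if (right) -1 else 1
    }
    next_offset <- sgn * 30 / 2^5
    final_offset <- (offsets[5] + next_offset) / 2
    structure(list(displayed_offsets = offsets, responses = responses,
                   final_offset = final_offset,
                   final_estimate = target + final_offset),
              class = "staircase_state")
  })
}

#' Full proprioceptive-judgment protocol
#'
#' 7 targets (0, +/-10, +/-20, +/-40 degrees) x 4 repetitions = 28 staircases
#' of 5 presentations each (140 presentations total), start side randomized
#' per staircase. `sigma_pj` is the SD of (final estimate - target) pooled
#' over all staircases.
#'
#' @param observer List with `bias` and `sd` (degrees) of the internal hand
#'   estimate.
#' @param seed Integer seed.
#' @return A list with `sigma_pj`, `estimates` (per-staircase data frame) and
#'   `n_presentations` (always 140).
#' @export
pj_protocol <- function(observer, seed) {
  targets <- rep(c(0, -10, 10, -20, 20, -40, 40), each = 4)
  order <- with_seed(derive_seed(seed, 1L), sample.int(length(targets)))
  targets <- targets[order]
  starts <- with_seed(derive_seed(seed, 2L),
                      sample(c(-1, 1), length(targets), replace = TRUE))
  est <- vapply(seq_along(targets), function(i) {
    pj_staircase(observer$bias, observer$sd, targets[i], starts[i],
                 derive_seed(seed, 10L + i))$final_offset
  }, numeric(1))
  list(
    sigma_pj = stats::sd(est),
    estimates = data.frame(target_deg = targets, start_sign = starts,
                           final_offset_deg = est),
    n_presentations = length(targets) * 5L
  )
}

#' Open-loop reaching protocol
#'
#' 5 targets (0, +/-20, +/-40 degrees) x 10 repetitions = 50 reaches without
#' visual feedback; endpoints are `target + N(bias, sd)`. `sigma_ol` is the SD
#' of endpoint errors after removing the per-target mean.
#'
#' @param observer List with `bias` and `sd` (degrees) of open-loop reaching.
#' @param seed Integer seed.
#' @return A list with `sigma_ol`, `trials` (data frame) and `n_trials` (50).
#' @export
ol_protocol <- function(observer, seed) {
  targets <- rep(c(0, -20, 20, -40, 40), each = 10)
  with_seed(seed, {
    targets <- targets[sample.int(length(targets))]
    err <- observer$bias + observer$sd * stats::rnorm(length(targets))
    demeaned <- err - stats::ave(err, targets)
    list(
      sigma_ol = stats::sd(demeaned),
      trials = data.frame(target_deg = targets, error_deg = err),
      n_trials = length(targets)
    )
  })
}

#' Midline-judgment protocol
#'
#' 9 reports of the position perceived as aligned with the body midline; each
#' report is `N(bias, sd)`. Starting positions of the moving sphere are drawn
#' from +/-45, +/-40, +/-35, +/-30 degrees (randomized; they do not influence
#' the report distribution, only the trial metadata). `sigma_mj` is the SD of
#' the 9 reports.
#'
#' @param observer List with `bias` and `sd` (degrees) of the midline report.
#' @param seed Integer seed.
#' @return A list with `sigma_mj`, `trials` (data frame) and `n_trials` (9).
#' @export
mj_protocol <- function(observer, seed) {
  start_set <- c(-45, -40, -35, -30, 30, 35, 40, 45)
  with_seed(seed, {
    starts <- sample(start_set, 9, replace = TRUE)
    reports <- observer$bias + observer$sd * stats::rnorm(9)
    list(
      sigma_mj = stats::sd(reports),
      trials = data.frame(start_deg = starts, report_deg = reports),
      n_trials = 9L
    )
  })
}
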