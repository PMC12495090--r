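# Two-point discrimination (2PD) adaptive staircase with confirmation phase.

tpd_start_cm <- c(hand = 2, forearm = 4)

#' Two-point discrimination staircase
#'
#' Adaptive estimation of the tactile two-point threshold. Double-post probes
#' start at 2 cm (hand) or 4 cm (forearm); the separation is halved after each
#' run of three successive correct ("two points") responses; after an error
#' the separation rises to the midpoint of the erroneous separation and the
#' most recent correctly perceived one; a 150% increase applies only when the
#' starting separation itself is perceived as one point (no correct trial to
#' take a midpoint with). The run terminates after 5 inversions (changes of
#' direction of the separation sequence); the threshold estimate is the mean
#' of the last two correctly perceived separations. A confirmation phase then
#' delivers 5 double and 5 single posts at the estimate in random order and
#' accepts it if fewer than 3 responses are wrong, otherwise the staircase is
#' rerun (up to `max_attempts`).
#'
#' The simulated observer reports "two points" iff the separation is at or
#' above its true threshold, with an optional lapse rate flipping responses.
#' A deterministic observer with a threshold at (or below) the minimum
#' representable separation never errs, so the separation pins to
#' `min_separation`; such runs terminate after `floor_patience` trials at the
#' floor and are flagged `floored`.
#'
#' @param observer_threshold True two-point threshold, cm (`> 0`).
#' @param site `"hand"` or `"forearm"` (sets the starting separation).
#' @param seed Integer seed (used by the lapse process, start randomization of
#'   the confirmation phase, and reruns).
#' @param lapse Probability of a response flip (default 0).
#' @param min_separation Smallest deliverable separation, cm (default 0.1,
#'   i.e. 1 mm).
#' @param max_trials Safety cap on staircase trials.
#' @param max_attempts Maximum staircase runs if confirmation fails.
#' @param floor_patience Consecutive floor trials after which a run is
#'   declared floored.
#' @return A list of class `tpd_state`: `separations`, `outcomes`
#'   (`correct`/`error`), `inversions`, `threshold` (cm), `floored`,
#'   `confirmed`, `attempts`.
#' @export
tpd_staircase <- function(observer_threshold, site = c("hand", "forearm"),
                          seed = 1, lapse = 0, min_separation = 0.1,
                          max_trials = 10000, max_attempts = 3,
                          floor_patience = 30) {
  site <- match.arg(site)
  if (observer_threshold <= 0) {
    stop("`observer_threshold` must be > 0", call. = FALSE)
  }
  respond_two <- function(sep, u) {
    base <- sep >= observer_threshold
    if (u < lapse) !base else base
  }
  run_once <- function(run_seed) {
    with_seed(run_seed, {
      start <- tpd_start_cm[[site]]
      sep <- start
      seps <- numeric(0); outcomes <- character(0)
      inversions <- 0L
      last_dir <- 0L
      correct_streak <- 0L
      last_correct <- NA_real_
      floor_run <- 0L
      floored <- FALSE
      while (length(seps) < max_trials) {
        ok <- respond_two(sep, stats::runif(1))
        seps <- c(seps, sep); outcomes <- c(outcomes, if (ok) "correct" else "error")
        if (ok) {
          last_correct <- sep
          correct_streak <- correct_streak + 1L
          if (sep <= min_separation) floor_run <- floor_run + 1L else floor_run <- 0L
          if (floor_run >= floor_patience) { floored <- TRUE; break }
          if (correct_streak == 3L) {
            new_sep <- max(min_separation, sep / 2)
            correct_streak <- 0L
          } else new_sep <- sep
        } else {
          correct_streak <- 0L
          floor_run <- 0L
          new_sep <- if (is.na(last_correct)) 1.5 * sep
                     else (sep + last_correct) / 2
        }
        dir <- sign(new_sep - sep)
        if (dir != 0) {
          if (last_dir != 0 && dir != last_dir) inversions <- inversions + 1L
          last_dir <- dir
        }
        sep <- new_sep
        if (inversions >= 5L) break
      }
      corr_seps <- seps[outcomes == "correct"]
      threshold <- if (length(corr_seps) >= 2) {
        mean(utils::tail(corr_seps, 2))
      } else if (length(corr_seps) == 1) corr_seps else NA_real_
      list(separations = seps, outcomes = outcomes, inversions = inversions,
           threshold = threshold, floored = floored)
    })
  }
  confirm <- function(threshold, conf_seed) {
    with_seed(conf_seed, {
      probes <- sample(rep(c("double", "single"), each = 5))
      u <- stats::runif(10)
      errors <- 0L
      for (i in seq_along(probes)) {
        if (probes[i] == "double") {
          if (!respond_two(threshold, u[i])) errors <- errors + 1L
        } else {
          # single post: "two" is an error; lapse flips the veridical "one"
          if (u[i] < lapse) errors <- errors + 1L
        }
      }
      errors < 3L
    })
  }
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    st <- run_once(derive_seed(seed, attempt))
    ok <- !is.na(st$threshold) &&
      confirm(st$threshold, derive_seed(seed, 100L + attempt))
    if (ok || attempt >= max_attempts) break
  }
  structure(c(st, list(confirmed = ok, attempts = attempt, site = site)),
            class = "tpd_state")
}
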