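# Metric body representation: landmark geometry, estimated-dimension (ED) and
# estimated-error (EE) indices, and the group-comparison stage.

landmark_names <- c("index_tip", "ring_tip", "internal_wrist",
                    "external_wrist", "elbow")

#' Construct a set of five 2-D upper-limb landmarks
#'
#' Coordinates (cm, task-table frame) of the tip of the index, tip of the
#' ring finger, internal and external wrist, and elbow, for either the real or
#' the perceived limb. Real and perceived sets must share the frame.
#'
#' @param index_tip,ring_tip,internal_wrist,external_wrist,elbow Numeric
#'   length-2 `(x, y)` coordinates in cm.
#' @param flavor `"real"` or `"perceived"`.
#' @return A 5x2 matrix of class `landmark_set` with a `flavor` attribute.
#' @export
landmark_set <- function(index_tip, ring_tip, internal_wrist, external_wrist,
                         elbow, flavor = c("real", "perceived")) {
  flavor <- match.arg(flavor)
  args <- list(index_tip, ring_tip, internal_wrist, external_wrist, elbow)
  ok <- vapply(args, function(p) {
    is.numeric(p) && length(p) == 2 && all(is.finite(p))
  }, logical(1))
  if (!all(ok)) {
    stop("each landmark must be a finite (x, y) pair", call. = FALSE)
  }
  pts <- do.call(rbind, args)
  rownames(pts) <- landmark_names
  colnames(pts) <- c("x_cm", "y_cm")
  structure(pts, class = "landmark_set", flavor = flavor)
}

point_dist <- function(pts, a, b) {
  sqrt(sum((pts[a, ] - pts[b, ])^2))
}

#' Limb dimensions from landmark coordinates
#'
#' Euclidean distances between landmarks:
#' * `arm_length`: mean of internal-wrist to elbow and external-wrist to elbow;
#' * `arm_width`: internal wrist to external wrist;
#' * `hand_width`: index tip to ring tip;
#' * `hand_length`: mean of ring tip to external wrist and index tip to
#'   internal wrist (the pairing that uses all four finger/wrist landmarks
#'   consistently).
#'
#' @param landmarks A [landmark_set()].
#' @return Named numeric vector (cm) for `hand_length`, `hand_width`,
#'   `arm_length`, `arm_width`. A warning is emitted when coincident landmarks
#'   produce a zero dimension.
#' @export
limb_dimensions <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  dims <- c(
    hand_length = mean(c(point_dist(landmarks, "ring_tip", "external_wrist"),
                         point_dist(landmarks, "index_tip", "internal_wrist"))),
    hand_width = point_dist(landmarks, "index_tip", "ring_tip"),
    arm_length = mean(c(point_dist(landmarks, "internal_wrist", "elbow"),
                        point_dist(landmarks, "external_wrist", "elbow"))),
    arm_width = point_dist(landmarks, "internal_wrist", "external_wrist")
  )
  if (any(dims == 0)) {
    warning("degenerate geometry: coincident landmarks give a zero dimension",
            call. = FALSE)
  }
  dims
}

#' Estimated-dimension and estimated-error indices
#'
#' For each body part, `ed = perceived / real` (1 = veridical, < 1 =
#' underestimation) and `ee = |ed - 1|` (direction-free distortion, lowest
#' value 0).
#'
#' @param real,perceived [landmark_set()] objects of matching frame with
#'   flavors `"real"` and `"perceived"`.
#' @return A data frame with `body_part`, `perceived_cm`, `real_cm`, `ed`,
#'   `ee`.
#' @export
dimension_indices <- function(real, perceived) {
  stopifnot(inherits(real, "landmark_set"), inherits(perceived, "landmark_set"))
  if (!identical(attr(real, "flavor"), "real") ||
      !identical(attr(perceived, "flavor"), "perceived")) {
    stop("`real` and `perceived` flavors are mismatched", call. = FALSE)
  }
  rd <- limb_dimensions(real)
  pd <- limb_dimensions(perceived)
  if (any(rd == 0)) stop("zero real dimension: ED is undefined", call. = FALSE)
  data.frame(
    body_part = names(rd),
    perceived_cm = unname(pd),
    real_cm = unname(rd),
    ed = unname(pd / rd),
    ee = unname(abs(pd / rd - 1)),
    row.names = NULL
  )
}

#' Compare a dimension index between two groups
#'
#' Shapiro-Wilk normality check per group; if both are compatible with
#' normality (p > 0.05) an unpaired two-sample t test is used, otherwise a
#' rank-sum (Wilcoxon) test. The p value is Bonferroni-corrected by the number
#' of body parts tested (4 per index family).
#'
#' @param values Numeric index values (ED or EE).
#' @param group Factor/character of two group labels, parallel to `values`.
#' @param index_kind Label for the report (e.g. `"ed_arm_length"`).
#' @param n_tests Bonferroni correction factor (default 4).
#' @param alternative Passed to the location test.
#' @return A list with `index_kind`, `test` (`"t"` or `"wilcoxon"`),
#'   `statistic`, `p_value`, `p_corrected`, `normal` (per-group logical),
#'   `group_means`, `degenerate` (TRUE when a normality check could not be
#'   run, forcing the rank-sum branch).
#' @export
group_compare <- function(values, group, index_kind = "index", n_tests = 4,
                          alternative = "two.sided") {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly two levels", call. = FALSE)
  split_vals <- split(values, group)
  if (any(vapply(split_vals, length, 1L) < 3)) {
    stop("need >= 3 observations per group", call. = FALSE)
  }
  degenerate <- FALSE
  normal <- vapply(split_vals, function(v) {
    p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    if (is.na(p)) degenerate <<- TRUE
    isTRUE(p > 0.05)
  }, logical(1))
  if (all(normal) && !degenerate) {
    tst <- stats::t.test(split_vals[[1]], split_vals[[2]],
                         alternative = alternative)
    test <- "t"
  } else {
    tst <- suppressWarnings(
      stats::wilcox.test(split_vals[[1]], split_vals[[2]],
                         alternative = alternative))
    test <- "wilcoxon"
  }
  list(index_kind = index_kind, test = test,
       statistic = unname(tst$statistic), p_value = tst$p.value,
       p_corrected = min(1, tst$p.value * n_tests),
       normal = normal,
       group_means = vapply(split_vals, mean, numeric(1)),
       degenerate = degenerate)
}
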