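# Predictor selection for arm-length misperception: zero-variance screening,
# LOOCV Lasso, and an OLS report on the retained variables.

#' Screen predictors for (near-)zero variance
#'
#' Drops every predictor column in which all but at most one participant share
#' a single value (the rule that removed the backward digit span from the
#' original analysis: "all subjects having the same equivalent score except
#' one"). Constant columns are a special case and are dropped too.
#'
#' @param table Data frame of predictors (the response column, if present, is
#'   never screened).
#' @param response Name of the response column to protect (default
#'   `"ee_arm_length"`).
#' @return A list with `table` (reduced data frame) and `excluded` (character
#'   vector naming dropped columns). Raises an error if screening removes
#'   every predictor.
#' @export
screen_predictors <- function(table, response = "ee_arm_length") {
  if (!nrow(table)) stop("`table` is empty", call. = FALSE)
  pred_cols <- setdiff(names(table), response)
  near_constant <- vapply(pred_cols, function(nm) {
    v <- table[[nm]]
    (length(v) - max(table(v))) <= 1
  }, logical(1))
  excluded <- pred_cols[near_constant]
  keep <- setdiff(names(table), excluded)
  if (!length(setdiff(keep, response))) {
    stop("screening removed every predictor: empty design", call. = FALSE)
  }
  list(table = table[, keep, drop = FALSE], excluded = excluded)
}

#' Lasso variable selection with leave-one-out cross-validation
#'
#' L1-penalized linear regression (`alpha = 1`) over a 100-value log-spaced
#' lambda path, with predictors standardized internally. The optimal lambda is
#' the LOOCV minimizer of mean squared error (`nfolds = n`, one fold per
#' participant, so the fold assignment is deterministic); the retained set is
#' the predictors with nonzero coefficients at that lambda.
#'
#' @param table Data frame containing the predictors and the response.
#' @param response Name of the response column.
#' @param seed Integer seed (kept for interface uniformity; LOOCV folds are
#'   deterministic).
#' @return A list with `lambda_star`, `retained` (character vector, possibly
#'   empty), `coefficients` (at `lambda_star`) and the `cv_fit` object.
#' @export
lasso_select <- function(table, response = "ee_arm_length", seed = 1) {
  pred_cols <- setdiff(names(table), response)
  n <- nrow(table)
  if (n < 10) stop("need n >= 10 participants", call. = FALSE)
  x <- as.matrix(table[, pred_cols, drop = FALSE])
  y <- table[[response]]
  if (qr(scale(x, scale = FALSE))$rank < ncol(x)) {
    warning("design is rank deficient after screening; path still computed",
            call. = FALSE)
  }
  cv <- with_seed(seed, {
    glmnet::cv.glmnet(x, y, alpha = 1, nfolds = n, foldid = seq_len(n),
                      grouped = FALSE, standardize = TRUE, nlambda = 100)
  })
  co <- stats::coef(cv, s = "lambda.min")
  co <- stats::setNames(as.numeric(co), rownames(co))
  retained <- setdiff(names(co)[co != 0], "(Intercept)")
  list(lambda_star = cv$lambda.min, retained = retained,
       coefficients = co, cv_fit = cv)
}

#' OLS report on the retained predictors
#'
#' Unpenalized least squares of the response on the Lasso-retained terms, with
#' the usual coefficient table, R-squared, adjusted R-squared, overall F test
#' and Cohen's `f2 = R2 / (1 - R2)`.
#'
#' @param table Data frame containing predictors and response.
#' @param retained Character vector of retained predictor names (nonempty).
#' @param response Name of the response column.
#' @return A list with `coefficients` (data frame: estimate, se, t, p),
#'   `r_squared`, `adj_r_squared`, `f_statistic` (`value`, `df1`, `df2`,
#'   `p_value`), `cohens_f2`, and the fitted `model`.
#' @export
ols_report <- function(table, retained, response = "ee_arm_length") {
  if (!length(retained)) stop("`retained` must be nonempty", call. = FALSE)
  if (nrow(table) <= length(retained) + 1) {
    stop("need n > p + 1 for the OLS report", call. = FALSE)
  }
  x <- as.matrix(table[, retained, drop = FALSE])
  if (qr(x)$rank < ncol(x)) {
    cc <- stats::cor(x)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop(sprintf("singular design: `%s` and `%s` are collinear",
                 retained[worst[1]], retained[worst[2]]), call. = FALSE)
  }
  fml <- stats::reformulate(retained, response = response)
  fit <- stats::lm(fml, data = table)
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "t", "p")
  fs <- sm$fstatistic
  list(
    coefficients = ct,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = list(value = unname(fs[1]), df1 = unname(fs[2]),
                       df2 = unname(fs[3]),
                       p_value = unname(stats::pf(fs[1], fs[2], fs[3],
                                                  lower.tail = FALSE))),
    cohens_f2 = sm$r.squared / (1 - sm$r.squared),
    model = fit
  )
}

#' Normalize cognitive-flexibility scores across populations
#'
#' Emulates the two-stage normalization of timed cognitive scores collected in
#' different reference populations: z-scoring within each population, then
#' z-scoring the pooled values.
#'
#' @param raw Numeric raw scores (e.g. completion-time differences, seconds).
#' @param population Character/factor labels of the reference population.
#' @return Numeric vector of pooled z scores.
#' @export
normalize_across_populations <- function(raw, population) {
  population <- as.factor(population)
  within <- unsplit(lapply(split(raw, population), function(v) {
    if (length(v) < 2 || stats::sd(v) == 0) v - mean(v) else as.numeric(scale(v))
  }), population)
  as.numeric(scale(within))
}
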