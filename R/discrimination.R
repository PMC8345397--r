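#' Area under the ROC curve (rank formulation)
#'
#' AUC computed as the Mann-Whitney U statistic over all case-control pairs,
#' with ties counting one half: the probability a random case outranks a
#' random control. Invariant under strictly monotone transforms of the score.
#'
#' @param score Numeric score vector.
#' @param status Binary (0/1 or logical) case status, same length.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(score, status) {
  if (is.logical(status)) status <- as.integer(status)
  keep <- !is.na(score) & !is.na(status)
  score <- score[keep]; status <- status[keep]
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(score, ties.method = "average")
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a fitted logistic model
#'
#' Fits `outcome ~ predictors` by logistic regression and returns the AUC of
#' the fitted probabilities (equal to the AUC of the linear predictor).
#'
#' @param data Data frame.
#' @param outcome Binary outcome column name.
#' @param predictors Predictor column names.
#' @return AUC in \[0, 1\].
#' @export
model_auc <- function(data, outcome, predictors) {
  fit <- fit_logistic(data, outcome, predictors)
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  used <- as.integer(rownames(stats::model.frame(fit$fit)))
  auc(stats::fitted(fit$fit), y[used])
}

# Fitted probabilities from a logistic model, tolerating aliased columns
# (glm's pivoting already yields correct predictions on the column span).
logistic_predictions <- function(data, outcome, predictors) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  X <- purrr::map_dfc(data[, predictors, drop = FALSE], function(col) {
    if (is.character(col) || is.factor(col)) as.integer(factor(col)) - 1L else as.numeric(col)
  })
  keep <- stats::complete.cases(X) & !is.na(y)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, as.matrix(X[keep, , drop = FALSE])),
                   y[keep], family = stats::binomial())
  )
  list(p = fit$fitted.values, y = y[keep])
}

#' Observed-scale variance explained
#'
#' Linear-model R-squared of the 0/1 outcome on the design columns — the
#' observed-scale R^2 convention used by the liability transformation. For a
#' single predictor this is the squared Pearson correlation between outcome
#' and predictor.
#'
#' @param data Data frame.
#' @param outcome Binary outcome column name.
#' @param predictors Predictor column names.
#' @return R-squared in \[0, 1\] (0 for a constant predictor).
#' @export
observed_r2 <- function(data, outcome, predictors) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) < 2) stop("outcome has a single class")
  X <- purrr::map_dfc(data[, predictors, drop = FALSE], function(col) {
    if (is.character(col) || is.factor(col)) as.integer(factor(col)) - 1L else as.numeric(col)
  })
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- as.matrix(X[keep, , drop = FALSE]); y <- y[keep]
  if (all(apply(X, 2, function(c) stats::var(c) == 0))) return(0)
  fit <- stats::lm.fit(cbind(1, X), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  max(0, 1 - sse / sst)
}

#' Liability-threshold context
#'
#' Precomputes the quantities of the liability-threshold model used to move
#' variance explained from the observed 0/1 scale to the liability scale
#' under case-control ascertainment: threshold `t = qnorm(1 - K)`, normal
#' density `z` at `t`, and mean case liability `i = z/K`.
#'
#' @param K Population disease prevalence in (0, 1).
#' @param P Case fraction in the analysed sample in (0, 1).
#' @return List with `K`, `P`, `t`, `z`, `i`.
#' @export
liability_context <- function(K, P) {
  if (K <= 0 || K >= 1) stop("prevalence K must be in (0, 1)")
  if (P <= 0 || P >= 1) stop("sample case fraction P must be in (0, 1)")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  list(K = K, P = P, t = t, z = z, i = z / K)
}

#' Observed-scale to liability-scale R-squared
#'
#' Ascertainment-corrected transformation for case-control samples whose
#' case fraction `P` exceeds the population prevalence `K`:
#' \deqn{C = \frac{[K(1-K)]^2}{z^2\,P(1-P)},\quad
#'       u = i\frac{P-K}{1-K},\quad \theta = u(u - t),\quad
#'       R^2_l = \frac{C\,R^2_o}{1 + C\,\theta\,R^2_o}.}
#' At `K = P` the correction reduces to the classical scale factor
#' `K(1-K)/z^2 * K(1-K)/(P(1-P))`; at `K = P = 0.5` that is exactly
#' `pi/2`.
#'
#' @param r2_obs Observed-scale R-squared in \[0, 1).
#' @param ctx Context from [liability_context()].
#' @return Liability-scale R-squared, clamped to \[0, 1\] with a warning if
#'   clamping was needed.
#' @export
liability_r2 <- function(r2_obs, ctx) {
  if (r2_obs < 0 || r2_obs >= 1) stop("r2_obs must be in [0, 1)")
  C <- (ctx$K * (1 - ctx$K))^2 / (ctx$z^2 * ctx$P * (1 - ctx$P))
  u <- ctx$i * (ctx$P - ctx$K) / (1 - ctx$K)
  theta <- u * (u - ctx$t)
  out <- C * r2_obs / (1 + C * theta * r2_obs)
  if (out < 0 || out > 1) {
    warning("liability-scale R2 ", format(out, digits = 4), " clamped to [0, 1]")
    out <- min(1, max(0, out))
  }
  out
}

#' Leave-one-covariate-out contribution decomposition
#'
#' For each predictor in the full model, refits the model without it and
#' reports `contribution = metric(full) - metric(reduced)` — the added value
#' of that variable — for either the AUC or the liability-scale R-squared.
#' Contributions are reported in percentage points.
#'
#' @param data Data frame.
#' @param outcome Binary outcome column name.
#' @param predictors Predictor column names of the full model (>= 2).
#' @param metric `"auc"` or `"liability_r2"`.
#' @param ctx Liability context (required for `metric = "liability_r2"`).
#' @return Tibble: `variable`, `metric_full`, `metric_reduced`,
#'   `contribution`, `contribution_pct`.
#' @export
contribution_decomposition <- function(data, outcome, predictors,
                                       metric = c("auc", "liability_r2"),
                                       ctx = NULL) {
  metric <- match.arg(metric)
  if (length(predictors) < 2) stop("need at least two predictors to decompose")
  eval_metric <- function(preds) {
    if (metric == "auc") {
      # tolerant fit: a duplicated/aliased column does not change the model
      # span, so it must contribute ~0 rather than abort the decomposition
      pr <- logistic_predictions(data, outcome, preds)
      auc(pr$p, pr$y)
    } else {
      if (is.null(ctx)) stop("liability context required for metric = 'liability_r2'")
      liability_r2(observed_r2(data, outcome, preds), ctx)
    }
  }
  full <- eval_metric(predictors)
  purrr::map_dfr(predictors, function(v) {
    reduced <- eval_metric(setdiff(predictors, v))
    tibble::tibble(variable = v, metric = metric,
                   metric_full = full, metric_reduced = reduced,
                   contribution = full - reduced,
                   contribution_pct = 100 * (full - reduced))
  })
}
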