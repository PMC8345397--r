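#' Welch's two-sample t-test, tidied
#'
#' Two-sided unequal-variance t-test comparing group means, returned as a
#' one-row tibble (statistic, Welch-Satterthwaite df, p).
#'
#' @param x,y Numeric samples, each with at least two observations.
#' @return Tibble: `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1,
                            mean_x = mean(x), mean_y = mean(y)))
    }
    stop("zero variance in both samples")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared with 1 df and no continuity correction, which is the
#' form that reproduces published contingency p-values in this analysis:
#' \eqn{\chi^2 = n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}.
#'
#' @param table 2x2 numeric matrix of non-negative counts (rows = exposure
#'   groups, columns = outcome levels).
#' @return Tibble: `chi2`, `p_value`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("negative cell count")
  if (sum(table) == 0) stop("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal: chi-squared statistic undefined")
  }
  # asymptotic test by design, matching the published analysis; the
  # small-expected-count approximation warning is therefore not surfaced
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), p_value = ct$p.value)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' @param table 2x2 count matrix `rbind(c(a, b), c(c, d))`; OR = ad/(bc),
#'   95% CI `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' @param haldane Add 0.5 to every cell when a zero cell is present
#'   (Haldane-Anscombe); default `FALSE`, in which case zero cells error.
#' @return Tibble: `or`, `ci_low`, `ci_high`, `p_value` (Wald).
#' @export
crude_or <- function(table, haldane = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table == 0)) {
    if (!haldane) stop("zero cell: crude OR undefined (set haldane = TRUE to add 0.5)")
    table <- table + 0.5
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - 1.96 * se),
    ci_high = exp(log_or + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(log_or / se))
  )
}

#' Logistic regression fit with Wald summaries
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`). Errors explicitly on rank-deficient designs and on
#' (quasi-)separation instead of returning silently degenerate estimates.
#'
#' @param data Data frame with the outcome and predictor columns.
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param predictors Character vector of predictor column names.
#' @return Object of class `crcprs_logit`: the `glm` fit plus a tidy
#'   coefficient table with Wald ORs, 95% CIs and p-values.
#' @export
fit_logistic <- function(data, outcome, predictors) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (anyDuplicated(predictors)) {
    stop("rank-deficient design: predictor '",
         predictors[duplicated(predictors)][1], "' appears more than once")
  }
  df <- tibble::tibble(.y = y)
  if (length(predictors) > 0) {
    X <- purrr::map_dfc(data[, predictors, drop = FALSE], function(col) {
      if (is.character(col) || is.factor(col)) as.integer(factor(col)) - 1L else as.numeric(col)
    })
    df <- dplyr::bind_cols(df, X)
  }
  fml <- if (length(predictors) == 0) {
    stats::as.formula(".y ~ 1")
  } else {
    stats::as.formula(paste(".y ~", paste0("`", predictors, "`", collapse = " + ")))
  }
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect or quasi-perfect separation detected in logistic fit", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) stop("logistic fit did not converge within 100 IRLS iterations")
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: aliased coefficient(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  sm <- unname(summary(fit)$coefficients)
  coefs <- tibble::tibble(
    term = names(stats::coef(fit)),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4],
    or = exp(sm[, 1]),
    ci_low = exp(sm[, 1] - 1.96 * sm[, 2]),
    ci_high = exp(sm[, 1] + 1.96 * sm[, 2])
  )
  structure(list(fit = fit, coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, n = length(y)),
            class = "crcprs_logit")
}

#' @export
print.crcprs_logit <- function(x, ...) {
  cat("Logistic fit (n = ", x$n, ", logLik = ", format(x$log_likelihood, digits = 6), ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Covariate-adjusted OR for one exposure
#'
#' Fits `outcome ~ exposure + covariates` and extracts the exposure row.
#'
#' @param data Data frame.
#' @param outcome,exposure Column names (outcome binary).
#' @param covariates Character vector of covariate column names (may be
#'   empty for a crude logistic OR).
#' @return One-row tibble with `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
adjusted_or <- function(data, outcome, exposure, covariates = c("age", "sex")) {
  fit <- fit_logistic(data, outcome, c(exposure, covariates))
  row <- fit$coefficients[fit$coefficients$term == paste0("`", exposure, "`") |
                            fit$coefficients$term == exposure, ]
  if (nrow(row) == 0) row <- fit$coefficients[2, ]
  dplyr::select(row, or, ci_low, ci_high, p_value)
}

#' Per-quantile odds-ratio profile
#'
#' For each score quantile, estimates the OR of case status versus the
#' reference (median) quantile from a logistic model on the individuals of
#' the two quantiles, with the requested covariates. The reference quantile
#' has OR fixed at 1.
#'
#' @param scored Tibble from [compute_wprs()] (needs `quantile`, `group`).
#' @param case_group,control_group Group labels defining cases and controls.
#' @param covariates Covariate column names (default age and sex).
#' @param reference_q Reference quantile; default 10 (median of 20).
#' @return Tibble with one row per quantile: `quantile`, `n_cases`,
#'   `n_controls`, `or`, `ci_low`, `ci_high`, `p_value`, `reference`.
#' @export
quantile_or_profile <- function(scored, case_group = "fcrc", control_group = "control",
                                covariates = c("age", "sex"), reference_q = 10) {
  d <- scored[!is.na(scored$quantile) & scored$group %in% c(case_group, control_group), ]
  d$case <- as.integer(d$group == case_group)
  qs <- sort(unique(d$quantile))
  if (!reference_q %in% qs) stop("reference quantile ", reference_q, " not present")
  ref <- d[d$quantile == reference_q, ]
  rows <- purrr::map_dfr(qs, function(q) {
    nq <- d[d$quantile == q, ]
    base <- tibble::tibble(quantile = q,
                           n_cases = sum(nq$case), n_controls = sum(1 - nq$case))
    if (q == reference_q) {
      return(dplyr::mutate(base, or = 1, ci_low = NA_real_, ci_high = NA_real_,
                           p_value = NA_real_, reference = TRUE))
    }
    # an empty case or control arm in either quantile leaves the OR
    # unidentified (quasi-separation); mark it rather than report a
    # numerically divergent estimate
    if (base$n_cases + base$n_controls == 0 ||
        min(base$n_cases, base$n_controls) == 0 ||
        min(sum(ref$case), sum(1 - ref$case)) == 0 ||
        length(unique(c(nq$case, ref$case))) < 2) {
      return(dplyr::mutate(base, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                           p_value = NA_real_, reference = FALSE))
    }
    sub <- dplyr::bind_rows(nq, ref)
    sub$in_q <- as.integer(sub$quantile == q)
    est <- tryCatch(
      adjusted_or(sub, "case", "in_q", covariates),
      error = function(e) tibble::tibble(or = NA_real_, ci_low = NA_real_,
                                         ci_high = NA_real_, p_value = NA_real_)
    )
    dplyr::bind_cols(base, est, tibble::tibble(reference = FALSE))
  })
  attr(rows, "reference_quantile") <- reference_q
  rows
}

#' Interaction of the score with a binary modifier
#'
#' Wald test of the product term in
#' `outcome ~ wprs * modifier + covariates`.
#'
#' @param data Data frame with the columns named below.
#' @param outcome Binary outcome column name.
#' @param score Score column name.
#' @param modifier Binary (two-level) modifier column name.
#' @param covariates Covariate column names.
#' @return One-row tibble: `estimate` (product-term log-OR), `std_error`,
#'   `p_value`.
#' @export
interaction_test <- function(data, outcome, score = "wprs", modifier,
                             covariates = c("age", "sex")) {
  m <- data[[modifier]]
  if (is.character(m) || is.factor(m)) m <- as.integer(factor(m)) - 1L
  if (is.logical(m)) m <- as.integer(m)
  if (length(unique(m[!is.na(m)])) != 2) stop("modifier must have exactly two observed levels")
  d <- data
  d[[modifier]] <- m
  d$.interaction <- d[[score]] * m
  fit <- fit_logistic(d, outcome, c(score, modifier, covariates, ".interaction"))
  row <- fit$coefficients[grepl(".interaction", fit$coefficients$term, fixed = TRUE), ]
  tibble::tibble(estimate = row$estimate, std_error = row$std_error, p_value = row$p_value)
}

#' Group-level score statistics against controls
#'
#' Per-group n, mean and SD of the score, the two-sided Welch t-test p-value
#' versus controls, and the covariate-adjusted OR per score unit
#' (risk-allele equivalent) from a logistic model of group membership versus
#' controls.
#'
#' @param scored Tibble from [compute_wprs()].
#' @param covariates Covariate column names for the logistic OR.
#' @return Tibble, one row per group (controls first).
#' @export
group_score_stats <- function(scored, covariates = c("age", "sex")) {
  d <- scored[scored$complete, ]
  ctrl <- d[d$group == "control", ]
  if (nrow(ctrl) == 0) stop("no controls in scored cohort")
  groups <- c("control", setdiff(unique(d$group), "control"))
  purrr::map_dfr(groups, function(gr) {
    sub <- d[d$group == gr, ]
    base <- tibble::tibble(group = gr, n = nrow(sub),
                           mean_wprs = mean(sub$wprs), sd_wprs = stats::sd(sub$wprs))
    if (gr == "control") {
      return(dplyr::mutate(base, t_p_value = NA_real_, or = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_, or_p_value = NA_real_))
    }
    tp <- welch_t_test(sub$wprs, ctrl$wprs)$p_value
    cc <- dplyr::bind_rows(sub, ctrl)
    cc$case <- as.integer(cc$group == gr)
    est <- adjusted_or(cc, "case", "wprs", covariates)
    dplyr::bind_cols(base, tibble::tibble(t_p_value = tp),
                     dplyr::rename(est, or_p_value = p_value))
  })
}
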