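#' Winner's-curse correction of a discovery effect size
#'
#' Discovery GWAS effect sizes selected for genome-wide significance are
#' biased away from zero. This returns the conditional maximum-likelihood
#' estimate of the true effect given that the variant passed the two-sided
#' significance threshold: with \eqn{c = \Phi^{-1}(1 - \alpha/2)}, it
#' maximises
#' \deqn{\ell(\beta) = \log\phi\!\big((\hat\beta - \beta)/se\big) -
#'   \log\big[\Phi(\beta/se - c) + \Phi(-\beta/se - c)\big],}
#' the log density of the observed estimate conditional on selection.
#' Shrinkage is always toward zero and the corrected magnitude never exceeds
#' the observed one.
#'
#' @param beta_hat Observed log-odds estimate(s); vectorised.
#' @param se Standard error(s) of `beta_hat`, recycled; must be positive.
#' @param alpha Two-sided selection significance level; default `5e-8`
#'   (genome-wide significance).
#' @return Corrected estimate(s), same length as `beta_hat`.
#' @export
winners_curse_correct <- function(beta_hat, se, alpha = 5e-8) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  se <- rep_len(se, length(beta_hat))
  if (any(se <= 0)) stop("se must be positive")
  cthr <- stats::qnorm(1 - alpha / 2)
  purrr::map2_dbl(beta_hat, se, function(bh, s) {
    if (bh == 0) return(0)
    loglik <- function(b) {
      stats::dnorm((bh - b) / s, log = TRUE) -
        log(stats::pnorm(b / s - cthr) + stats::pnorm(-b / s - cthr))
    }
    lo <- min(0, bh) - s
    hi <- max(0, bh) + s
    opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = .Machine$double.eps^0.5)
    if (!is.finite(opt$objective)) stop("winner's-curse correction did not converge for beta_hat = ", bh)
    b <- opt$maximum
    # conditional MLE shrinks toward 0; clip numerical overshoot past beta_hat
    if (abs(b) > abs(bh)) b <- bh
    if (sign(b) != sign(bh) && b != 0) b <- 0
    b
  })
}

#' Apply winner's-curse correction to a panel
#'
#' @param panel Panel tibble with a `se` column (discovery standard errors).
#' @param alpha Selection threshold passed to [winners_curse_correct()].
#' @return The panel with `beta` replaced by the corrected estimate and the
#'   original kept in `beta_raw`.
#' @export
correct_panel_weights <- function(panel, alpha = 5e-8) {
  if (!"se" %in% names(panel)) stop("panel has no 'se' column with discovery standard errors")
  panel$beta_raw <- panel$beta
  panel$beta <- winners_curse_correct(panel$beta, panel$se, alpha = alpha)
  panel
}

#' Raw weighted and unweighted scores
#'
#' Computes, per individual, the weighted sum of effect-allele dosages over
#' the included, non-missing panel variants (`raw_weighted`), the plain
#' risk-allele count (`raw_unweighted`) and the number of non-missing
#' variants. Missing dosages contribute nothing; individuals with zero
#' non-missing variants are flagged `complete = FALSE` and should be excluded
#' downstream.
#'
#' @param dosages Numeric matrix (individuals x variants), `NA` = missing.
#'   Column names must match the panel's `variant_id`s.
#' @param panel Panel tibble; only `included` rows are scored.
#' @return Tibble: `individual_id`, `raw_weighted`, `raw_unweighted`,
#'   `n_nonmissing`, `complete`.
#' @export
compute_raw_scores <- function(dosages, panel) {
  inc <- panel[panel$included, , drop = FALSE]
  missing_cols <- setdiff(inc$variant_id, colnames(dosages))
  if (length(missing_cols) > 0) {
    stop("dosage matrix lacks column(s) for included variant(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  g <- dosages[, inc$variant_id, drop = FALSE]
  obs <- !is.na(g)
  g0 <- ifelse(obs, g, 0)
  raw_weighted <- drop(g0 %*% inc$beta)
  raw_unweighted <- rowSums(g0)
  n_nonmissing <- rowSums(obs)
  if (any(n_nonmissing == 0)) {
    warning(sum(n_nonmissing == 0), " individual(s) with zero non-missing variants flagged")
  }
  tibble::tibble(
    individual_id = rownames(dosages),
    raw_weighted = as.numeric(raw_weighted),
    raw_unweighted = as.numeric(raw_unweighted),
    n_nonmissing = as.integer(n_nonmissing),
    complete = n_nonmissing > 0
  )
}

#' Control-anchoring rescale constants
#'
#' The final score is anchored so that the control mean of the weighted score
#' equals the control mean risk-allele count: one score unit is then a
#' "risk-allele equivalent". The constants are the control means of the
#' weighted and unweighted scores, their ratio, and the per-variant mean
#' weighted contribution in controls (used to rescale individuals with
#' missing genotypes without bias when weights and frequencies differ across
#' variants).
#'
#' @param dosages Dosage matrix used for scoring.
#' @param panel Panel tibble (included rows define the score).
#' @param cohort Cohort tibble; rows with `group == "control"` anchor the
#'   scale.
#' @return List with `control_mean_weighted`, `control_mean_unweighted`,
#'   `anchor_ratio`, and named vector `per_variant_control_mean`.
#' @export
compute_rescale_constants <- function(dosages, panel, cohort) {
  ctrl_ids <- cohort$individual_id[cohort$group == "control"]
  ctrl_ids <- intersect(ctrl_ids, rownames(dosages))
  if (length(ctrl_ids) == 0) stop("no controls available to anchor the score scale")
  inc <- panel[panel$included, , drop = FALSE]
  g <- dosages[ctrl_ids, inc$variant_id, drop = FALSE]
  per_variant_mean_dosage <- colMeans(g, na.rm = TRUE)
  if (any(is.nan(per_variant_mean_dosage))) {
    per_variant_mean_dosage[is.nan(per_variant_mean_dosage)] <- 0
  }
  per_variant_control_mean <- per_variant_mean_dosage * inc$beta
  names(per_variant_control_mean) <- inc$variant_id
  obs <- !is.na(g)
  control_mean_weighted <- mean(drop(ifelse(obs, g, 0) %*% inc$beta))
  control_mean_unweighted <- mean(rowSums(g, na.rm = TRUE))
  if (control_mean_weighted <= 0) stop("control mean weighted score is not positive; cannot anchor")
  list(
    control_mean_weighted = control_mean_weighted,
    control_mean_unweighted = control_mean_unweighted,
    anchor_ratio = control_mean_unweighted / control_mean_weighted,
    per_variant_control_mean = per_variant_control_mean
  )
}

#' Rescale raw scores to the control-anchored wPRS
#'
#' Two rescalings are composed. First the control anchoring: every weighted
#' score is multiplied by `anchor_ratio` so the control mean lands on the
#' risk-allele-count scale. Second the missingness correction: each
#' individual's score is inflated by the ratio of the total per-variant
#' control-mean contribution to the contribution of the variants that are
#' non-missing for that individual, so random missingness leaves the
#' population mean unchanged. Individuals with no missing variants satisfy
#' `wprs == raw_weighted * anchor_ratio` exactly.
#'
#' @param scores Tibble from [compute_raw_scores()].
#' @param constants List from [compute_rescale_constants()].
#' @param dosages The dosage matrix the scores were computed from (needed to
#'   know which variants are missing per individual).
#' @return `scores` with a `wprs` column appended.
#' @export
rescale_scores <- function(scores, constants, dosages) {
  pv <- constants$per_variant_control_mean
  g <- dosages[scores$individual_id, names(pv), drop = FALSE]
  obs <- !is.na(g)
  total <- sum(pv)
  nonmiss_sum <- drop(obs %*% pv)
  factor <- rep(NA_real_, nrow(scores))
  ok <- nonmiss_sum > 0
  factor[ok] <- total / nonmiss_sum[ok]
  if (any(!ok & scores$complete)) {
    warning(sum(!ok & scores$complete),
            " individual(s) with zero control-mean mass over observed variants flagged")
  }
  scores$wprs <- scores$raw_weighted * constants$anchor_ratio * factor
  scores$complete <- scores$complete & ok
  scores
}

#' Assign score quantiles
#'
#' Ranks individuals by score and cuts them into `n_quantiles` bins whose
#' sizes differ by at most one, lowest scores in bin 1. Ties are broken by
#' stable (input) order. Only individuals selected by `mask` (by default all)
#' define the ranking population; others get `NA`.
#'
#' @param wprs Numeric score vector.
#' @param n_quantiles Number of bins (>= 2); default 20.
#' @param mask Logical vector selecting the ranking population.
#' @return Integer vector of bin indices in `[1, n_quantiles]`, `NA` outside
#'   the mask.
#' @export
assign_quantiles <- function(wprs, n_quantiles = 20, mask = NULL) {
  if (n_quantiles < 2) stop("n_quantiles must be at least 2")
  if (is.null(mask)) mask <- rep(TRUE, length(wprs))
  idx <- which(mask & !is.na(wprs))
  n <- length(idx)
  if (n < n_quantiles) stop("fewer individuals (", n, ") than quantiles (", n_quantiles, ")")
  ord <- idx[order(wprs[idx])]   # stable sort: ties keep input order
  bounds <- floor(seq_len(n_quantiles) * n / n_quantiles)
  sizes <- diff(c(0L, bounds))
  out <- rep(NA_integer_, length(wprs))
  out[ord] <- rep.int(seq_len(n_quantiles), sizes)
  out
}

#' Score a cohort end to end
#'
#' Convenience wrapper: raw scores, control-anchored rescaling and quantile
#' assignment (ranking population = familial cases + controls, the groups the
#' quantile risk profile compares).
#'
#' @param dosages Dosage matrix (individuals x variants).
#' @param panel Filtered panel tibble.
#' @param cohort Cohort tibble aligned with `dosages` rows.
#' @param n_quantiles Quantile count for stratification; default 20.
#' @param quantile_groups Groups defining the ranking population.
#' @return Tibble: cohort columns joined with `raw_weighted`,
#'   `raw_unweighted`, `n_nonmissing`, `complete`, `wprs`, `quantile`.
#' @export
compute_wprs <- function(dosages, panel, cohort, n_quantiles = 20,
                         quantile_groups = c("fcrc", "control")) {
  scores <- compute_raw_scores(dosages, panel)
  constants <- compute_rescale_constants(dosages, panel, cohort)
  scores <- rescale_scores(scores, constants, dosages)
  out <- dplyr::inner_join(cohort, scores, by = "individual_id")
  mask <- out$group %in% quantile_groups & out$complete
  out$quantile <- assign_quantiles(out$wprs, n_quantiles = n_quantiles, mask = mask)
  attr(out, "constants") <- constants
  class(out) <- c("crcprs_scores", class(out))
  out
}
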