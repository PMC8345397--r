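#' High- versus low-score clinical comparison
#'
#' Compares familial cases in the high-score quantiles against those in the
#' low-score quantiles across the clinical features of the cohort table:
#' per-feature 2x2 counts, Pearson chi-squared p-value (no continuity
#' correction), crude OR with Woolf CI, and a covariate-adjusted logistic OR
#' (age and sex, minus whichever the feature itself encodes). The
#' intermediate quantile band is excluded from the comparison.
#'
#' @param scored Tibble from [compute_wprs()].
#' @param case_group Group whose members are compared; default `"fcrc"`.
#' @param high_q,low_q Quantile indices defining the high and low strata;
#'   defaults 17-20 and 1-10 of 20.
#' @return Tibble, one row per feature: counts, `chi2_p`, crude `or` and CI,
#'   adjusted OR columns (`adj_or`, `adj_ci_low`, `adj_ci_high`, `adj_p`).
#' @export
highlow_comparison <- function(scored, case_group = "fcrc",
                               high_q = 17:20, low_q = 1:10) {
  d <- scored[scored$group == case_group & !is.na(scored$quantile), ]
  d$stratum <- dplyr::case_when(
    d$quantile %in% high_q ~ "high",
    d$quantile %in% low_q ~ "low",
    TRUE ~ NA_character_
  )
  d <- d[!is.na(d$stratum), ]
  features <- list(
    gender = function(x) x$sex == "male",
    deceased_status = function(x) x$deceased == "alive",
    age_at_dx_ge50 = function(x) !is.na(x$age_at_dx) & x$age_at_dx >= 50,
    hnpcc_criteria_amsterdam = function(x) x$criteria == "amsterdam",
    fam_history_crc = function(x) x$fam_history_crc == "yes",
    multiple_primary_crc = function(x) x$multiple_crc,
    multiple_primary_any = function(x) x$multiple_any
  )
  features <- features[purrr::map_lgl(features, function(f) {
    !inherits(try(f(d), silent = TRUE), "try-error") && !all(is.na(f(d)))
  })]
  purrr::imap_dfr(features, function(f, name) {
    pos <- f(d)
    keep <- !is.na(pos)
    sub <- d[keep, ]; pos <- pos[keep]
    tab <- rbind(c(sum(pos[sub$stratum == "high"]), sum(!pos[sub$stratum == "high"])),
                 c(sum(pos[sub$stratum == "low"]), sum(!pos[sub$stratum == "low"])))
    chi <- tryCatch(pearson_chi2(tab)$p_value, error = function(e) NA_real_)
    cr <- tryCatch(crude_or(tab, haldane = TRUE), error = function(e)
      tibble::tibble(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_))
    covars <- setdiff(c("age", "sex"), c(if (name == "gender") "sex",
                                         if (name == "age_at_dx_ge50") "age"))
    sub$feature_pos <- as.integer(pos)
    sub$high <- as.integer(sub$stratum == "high")
    adj <- tryCatch(adjusted_or(sub, "feature_pos", "high", covars),
                    error = function(e) tibble::tibble(or = NA_real_, ci_low = NA_real_,
                                                       ci_high = NA_real_, p_value = NA_real_))
    tibble::tibble(feature = name,
                   high_pos = tab[1, 1], high_neg = tab[1, 2],
                   low_pos = tab[2, 1], low_neg = tab[2, 2],
                   chi2_p = chi,
                   or = cr$or, ci_low = cr$ci_low, ci_high = cr$ci_high,
                   adj_or = adj$or, adj_ci_low = adj$ci_low,
                   adj_ci_high = adj$ci_high, adj_p = adj$p_value)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the whole analysis from a configuration list: load (or simulate)
#' the panel, dosages and cohort; filter variants on imputation quality;
#' optionally winner's-curse-correct the weights; compute the
#' control-anchored score and quantiles; then produce the four result
#' blocks — per-group score statistics, the per-quantile OR profile,
#' the high-versus-low clinical comparison, and the AUC / liability-R2
#' contribution decomposition.
#'
#' @param config Named list (or path to a YAML/JSON file naming one) with
#'   either `input = list(panel=, dosages=, cohort=)` file paths or
#'   `simulate = list(...)` arguments for [sim_config()]. Optional entries:
#'   `r2_threshold` (0.3), `n_quantiles` (20), `reference_quantile` (10),
#'   `high_quantiles` (17:20), `low_quantiles` (1:10), `covariates`
#'   (`c("age","sex")`), `prevalence_K` (0.04), `winners_curse` (FALSE),
#'   `seed`.
#' @return Object of class `crcprs_report`: list with `group_stats`,
#'   `quantile_profile`, `highlow`, `decomposition`, `scored`,
#'   `exclusions`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml_read(config)
    }
  }
  cfg <- utils::modifyList(list(
    r2_threshold = 0.3, n_quantiles = 20, reference_quantile = 10,
    high_quantiles = 17:20, low_quantiles = 1:10,
    covariates = c("age", "sex"), prevalence_K = 0.04,
    winners_curse = FALSE, seed = 1L
  ), config)

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- do.call(sim_config, sim_args)
    cohort_data <- simulate_cohort(sim)
    panel <- cohort_data$panel
    dosages <- cohort_data$genotypes
    cohort <- cohort_data$cohort
  } else if (!is.null(cfg$input)) {
    panel <- read_weights_table(cfg$input$panel)
    cohort <- read_cohort_table(cfg$input$cohort)
    dosages <- if (grepl("\\.vcf(\\.gz)?$", cfg$input$dosages)) {
      read_dosages_vcf(cfg$input$dosages, panel)
    } else {
      read_dosage_matrix(cfg$input$dosages)
    }
  } else {
    stop("config must provide either 'input' file paths or a 'simulate' block")
  }

  panel <- filter_by_imputation_r2(panel, cfg$r2_threshold)
  if (isTRUE(cfg$winners_curse)) panel <- correct_panel_weights(panel)

  scored <- compute_wprs(dosages, panel, cohort, n_quantiles = cfg$n_quantiles)
  group_stats <- group_score_stats(scored, covariates = cfg$covariates)
  profile <- quantile_or_profile(scored, covariates = cfg$covariates,
                                 reference_q = cfg$reference_quantile)
  highlow <- highlow_comparison(scored, high_q = cfg$high_quantiles,
                                low_q = cfg$low_quantiles)

  cc <- scored[scored$group %in% c("fcrc", "control") & scored$complete, ]
  cc$case <- as.integer(cc$group == "fcrc")
  cc$age_model <- ifelse(cc$case == 1 & !is.na(cc$age_at_dx), cc$age_at_dx, cc$age)
  preds <- c("wprs", "age_model", "sex")
  ctx <- liability_context(cfg$prevalence_K, mean(cc$case))
  decomposition <- dplyr::bind_rows(
    contribution_decomposition(cc, "case", preds, metric = "auc"),
    contribution_decomposition(cc, "case", preds, metric = "liability_r2", ctx = ctx)
  )

  excl <- attr(panel, "exclusions")
  incomplete <- scored$individual_id[!scored$complete]
  exclusions <- dplyr::bind_rows(
    if (!is.null(excl) && nrow(excl) > 0) dplyr::mutate(excl, unit = "variant") else NULL,
    if (length(incomplete) > 0) tibble::tibble(variant_id = incomplete,
                                               reason = "no scorable genotypes",
                                               unit = "individual") else NULL
  )
  structure(list(
    group_stats = group_stats,
    quantile_profile = profile,
    highlow = highlow,
    decomposition = decomposition,
    scored = scored,
    exclusions = exclusions,
    provenance = list(seed = cfg$seed,
                      n_variants_included = sum(panel$included),
                      n_individuals = nrow(scored),
                      r2_threshold = cfg$r2_threshold,
                      package_version = as.character(utils::packageVersion("crcprs")))
  ), class = "crcprs_report")
}

yaml_read <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package; use a JSON config or a list")
  }
  yaml::read_yaml(path)
}

#' @export
print.crcprs_report <- function(x, ...) {
  cat("Polygenic score analysis report\n")
  cat("  individuals:", x$provenance$n_individuals,
      "| variants included:", x$provenance$n_variants_included, "\n\n")
  cat("Group score statistics:\n")
  print(x$group_stats)
  cat("\nContribution decomposition:\n")
  print(x$decomposition)
  invisible(x)
}

#' Write a report's tables to disk
#'
#' @param report A `crcprs_report`.
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    group_stats = file.path(dir, "group_stats.tsv"),
    quantile_profile = file.path(dir, "quantile_profile.tsv"),
    highlow = file.path(dir, "highlow_comparison.tsv"),
    decomposition = file.path(dir, "decomposition.tsv"),
    exclusions = file.path(dir, "exclusions.tsv"),
    provenance = file.path(dir, "provenance.json")
  )
  readr::write_tsv(report$group_stats, paths$group_stats, progress = FALSE)
  readr::write_tsv(report$quantile_profile, paths$quantile_profile, progress = FALSE)
  readr::write_tsv(report$highlow, paths$highlow, progress = FALSE)
  readr::write_tsv(report$decomposition, paths$decomposition, progress = FALSE)
  readr::write_tsv(report$exclusions, paths$exclusions, progress = FALSE)
  jsonlite::write_json(report$provenance, paths$provenance, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Recompute the packaged published-count fixtures
#'
#' The package ships the printed 2x2 clinical counts of the high- versus
#' low-score familial-case comparison and the per-group cohort summary of
#' the study it models. This recomputes every chi-squared p-value (4 dp),
#' the crude ORs, the male/female ratios and the multiple-primary-CRC
#' percentages from those counts and checks them against the published
#' values carried in the fixture files.
#'
#' @return List of class `crcprs_fixture_report`: `clinical` (per-feature
#'   recomputed p, crude OR, expected p, `pass`), `summary` (per-group
#'   ratio/percentage checks), `all_pass`.
#' @export
run_printed_fixtures <- function() {
  clin_path <- system.file("extdata", "highlow_clinical_counts.tsv", package = "crcprs")
  summ_path <- system.file("extdata", "cohort_group_summary.tsv", package = "crcprs")
  if (clin_path == "" || summ_path == "") stop("packaged fixture files not found")
  clin <- readr::read_tsv(clin_path, show_col_types = FALSE, progress = FALSE)
  summ <- readr::read_tsv(summ_path, show_col_types = FALSE, progress = FALSE)

  clinical <- purrr::pmap_dfr(clin, function(feature, pos_label, neg_label,
                                             high_pos, high_neg, low_pos, low_neg,
                                             expected_chi2_p) {
    tab <- rbind(c(high_pos, high_neg), c(low_pos, low_neg))
    p <- round(pearson_chi2(tab)$p_value, 4)
    cr <- crude_or(tab)
    tibble::tibble(feature = feature, chi2_p = p, expected_chi2_p = expected_chi2_p,
                   crude_or = cr$or, ci_low = cr$ci_low, ci_high = cr$ci_high,
                   pass = identical(p, expected_chi2_p))
  })
  summary_checks <- dplyr::mutate(
    summ,
    mf_ratio = round(male_n / female_n, 2),
    multiple_crc_pct = round(100 * multiple_crc_n / n, 2),
    ratio_pass = mf_ratio == expected_mf_ratio,
    pct_pass = is.na(expected_multiple_crc_pct) | multiple_crc_pct == expected_multiple_crc_pct
  )
  structure(list(clinical = clinical, summary = summary_checks,
                 all_pass = all(clinical$pass) &&
                   all(summary_checks$ratio_pass, na.rm = TRUE) &&
                   all(summary_checks$pct_pass, na.rm = TRUE)),
            class = "crcprs_fixture_report")
}

#' @export
print.crcprs_fixture_report <- function(x, ...) {
  cat("Published-count fixture checks:", if (x$all_pass) "all pass" else "FAILURES", "\n")
  print(x$clinical[, c("feature", "chi2_p", "expected_chi2_p", "crude_or", "pass")])
  invisible(x)
}
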