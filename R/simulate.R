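#' Simulation configuration
#'
#' Assembles and validates the knobs of the synthetic cohort generator. The
#' defaults mirror the familial/early-onset colorectal cancer case-control
#' design the package models: a 92-variant risk panel, group sizes
#' 417 familial cases / 80 serrated polyposis / 1077 sporadic cases / 1642
#' controls, group-specific age and sex distributions, a liability-threshold
#' disease model with prevalence 4% and a score liability-variance share of
#' 10%.
#'
#' @param n_variants Number of panel variants.
#' @param maf_range Effect-allele frequency range (uniform draw).
#' @param effect_model `"lognormal"` (log-normal magnitudes clamped to
#'   `logor_range`) or `"fixed"` (every beta equal to `fixed_logor`).
#' @param logor_range Per-allele log-OR magnitude range; the default
#'   0.02-0.18 spans typical common-variant colorectal cancer effects.
#' @param fixed_logor Per-allele log-OR used when `effect_model = "fixed"`.
#' @param prevalence_K Population disease prevalence.
#' @param disease_model `"liability_threshold"` or `"logistic"`.
#' @param h2_liability Liability variance share of the score (liability
#'   model).
#' @param n_population Population size simulated before ascertainment. The
#'   default 250,000 is sized so that affected-sibling ascertainment at 4%
#'   prevalence still yields the full familial case group.
#' @param group_sizes Named integer vector: `fcrc`, `sp`, `sporadic_crc`,
#'   `control`.
#' @param familial_rule `"affected_sib"` or `"none"`: how familial cases are
#'   ascertained.
#' @param missing_rate Independent genotype missingness rate.
#' @param genotyped_frac Fraction of panel variants flagged as directly
#'   genotyped (no imputation R2); default 13/95 as in a mixed
#'   array/imputation panel.
#' @param n_low_r2 Number of imputed variants forced below the 0.3
#'   imputation-quality cutoff; default 3.
#' @param age_sex_model Data frame of per-group age means/SDs and male
#'   fractions; defaults to the study-like values (familial cases mean age
#'   48.7 (12.4), controls 62.4 (10.25), control male fraction 0.51, ...).
#' @param seed Integer seed; mandatory, all generator randomness flows from
#'   it.
#' @return A validated list of class `crcprs_sim_config`.
#' @export
sim_config <- function(n_variants = 92,
                       maf_range = c(0.05, 0.5),
                       effect_model = c("lognormal", "fixed"),
                       logor_range = c(0.02, 0.18),
                       fixed_logor = log(1.10),
                       prevalence_K = 0.04,
                       disease_model = c("liability_threshold", "logistic"),
                       h2_liability = 0.10,
                       n_population = 250000,
                       group_sizes = c(fcrc = 417, sp = 80, sporadic_crc = 1077, control = 1642),
                       familial_rule = c("affected_sib", "none"),
                       missing_rate = 0.02,
                       genotyped_frac = 13 / 95,
                       n_low_r2 = 3,
                       age_sex_model = default_age_sex_model(),
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  effect_model <- match.arg(effect_model)
  disease_model <- match.arg(disease_model)
  familial_rule <- match.arg(familial_rule)
  stopifnot(n_variants >= 1,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            length(logor_range) == 2, logor_range[1] <= logor_range[2], logor_range[1] > 0,
            prevalence_K > 0, prevalence_K < 1,
            h2_liability >= 0, h2_liability < 1,
            missing_rate >= 0, missing_rate < 1,
            genotyped_frac >= 0, genotyped_frac <= 1,
            n_low_r2 >= 0)
  structure(list(
    n_variants = n_variants, maf_range = maf_range, effect_model = effect_model,
    logor_range = logor_range, fixed_logor = fixed_logor,
    prevalence_K = prevalence_K, disease_model = disease_model,
    h2_liability = h2_liability, n_population = n_population,
    group_sizes = group_sizes, familial_rule = familial_rule,
    missing_rate = missing_rate, genotyped_frac = genotyped_frac,
    n_low_r2 = n_low_r2, age_sex_model = age_sex_model, seed = as.integer(seed)
  ), class = "crcprs_sim_config")
}

#' Study-like per-group age and sex parameters
#'
#' @return Tibble: `group`, `age_mean`, `age_sd`, `male_frac`,
#'   `fam_history_crc_rate`, `multiple_crc_rate`.
#' @export
default_age_sex_model <- function() {
  tibble::tribble(
    ~group,         ~age_mean, ~age_sd, ~male_frac, ~fam_history_crc_rate, ~multiple_crc_rate,
    "fcrc",         48.72,     12.40,   0.5582,     0.5108,                0.0767,
    "sp",           52.29,     12.60,   0.6625,     0.3750,                0.1125,
    "sporadic_crc", 66.87,     10.88,   0.6518,     0.1226,                0.0,
    "control",      62.40,     10.25,   0.5085,     0.0512,                0.0
  )
}

#' Simulate a variant weight panel
#'
#' Draws effect-allele frequencies uniform on the configured range and
#' positive per-allele log-OR weights (effect alleles are risk alleles).
#' Imputation quality has a point mass of directly genotyped variants; the
#' remainder get a Beta-shaped R2 on (0.3, 1) except for `n_low_r2` variants
#' forced below 0.3 so the quality filter has work to do.
#'
#' @param config A [sim_config()] object.
#' @return Panel tibble in the format of [read_weights_table()], with the
#'   true weights in `beta`.
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  m <- config$n_variants
  eaf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  beta <- if (config$effect_model == "fixed") {
    rep(config$fixed_logor, m)
  } else {
    lo <- config$logor_range[1]; hi <- config$logor_range[2]
    raw <- stats::rlnorm(m, meanlog = mean(log(c(lo, hi))), sdlog = (log(hi) - log(lo)) / 4)
    pmin(pmax(raw, lo), hi)
  }
  # non-ambiguous allele pairs only; strand issues are exercised separately
  pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"))
  pick <- pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
  n_geno <- round(config$genotyped_frac * m)
  genotyped <- seq_len(m) %in% sample.int(m, n_geno)
  r2 <- rep(NA_real_, m)
  imputed_idx <- which(!genotyped)
  low_idx <- utils::head(sample(imputed_idx), min(config$n_low_r2, length(imputed_idx)))
  hi_idx <- setdiff(imputed_idx, low_idx)
  r2[hi_idx] <- 0.3 + 0.7 * stats::rbeta(length(hi_idx), 5, 1.2)
  r2[low_idx] <- stats::runif(length(low_idx), 0.05, 0.29)
  tibble::tibble(
    variant_id = sprintf("rs%07d", seq_len(m) * 13 + 1000000),
    chrom = as.character(rep_len(1:22, m)),
    pos = 1000000L + seq_len(m) * 37913L,
    effect_allele = pick[, 1],
    other_allele = pick[, 2],
    beta = beta,
    eaf = eaf,
    genotyped = genotyped,
    imputation_r2 = r2,
    included = TRUE
  )
}

#' Simulate genotype dosages
#'
#' Hard-call dosages drawn `Binomial(2, eaf)` independently per variant
#' (Hardy-Weinberg equilibrium, linkage equilibrium).
#'
#' @param panel Panel tibble.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated individual ids.
#' @return Numeric dosage matrix (n x variants) with dimnames.
#' @export
simulate_genotypes <- function(panel, n, seed, id_prefix = "ind") {
  set.seed(seed)
  m <- nrow(panel)
  g <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, panel$eaf[j]),
              numeric(n))
  if (n == 1L) g <- matrix(g, nrow = 1L)
  dimnames(g) <- list(sprintf("%s%06d", id_prefix, seq_len(n)), panel$variant_id)
  g
}

# Centered weighted genetic score and its theoretical SD under HWE/LE.
genetic_score <- function(genotypes, panel) {
  s <- drop(genotypes %*% panel$beta) - sum(2 * panel$eaf * panel$beta)
  sd_theory <- sqrt(sum(panel$beta^2 * 2 * panel$eaf * (1 - panel$eaf)))
  list(score = s, sd = sd_theory)
}

#' Assign disease status
#'
#' Logistic model: `P(case) = expit(alpha + sum beta_i (g_i - 2 eaf_i))`
#' with the intercept solved by bisection so the population mean case
#' probability equals the prevalence `K` (to 1e-4). Liability-threshold
#' model: standardized genetic score times `sqrt(h2)` plus independent
#' normal environment; case when liability exceeds `qnorm(1 - K)`.
#'
#' @param genotypes Dosage matrix.
#' @param panel Panel tibble (true weights in `beta`).
#' @param config [sim_config()] object (uses `disease_model`,
#'   `prevalence_K`, `h2_liability`).
#' @param seed Integer seed for the stochastic case assignment.
#' @param alpha Optional fixed logistic intercept. When `NULL` (default) the
#'   intercept is solved on `genotypes`; pass the population value when
#'   scoring a non-representative subset (e.g. siblings of cases), where
#'   re-solving would erase the enrichment.
#' @return List: `status` (integer 0/1), `truth` (list with the model,
#'   K, h2 or intercept, per-variant betas, and the latent liability or
#'   case probabilities).
#' @export
assign_status <- function(genotypes, panel, config, seed, alpha = NULL) {
  set.seed(seed)
  gs <- genetic_score(genotypes, panel)
  K <- config$prevalence_K
  if (config$disease_model == "logistic") {
    if (is.null(alpha)) {
      f <- function(a) mean(stats::plogis(a + gs$score)) - K
      lo <- -30; hi <- 10
      if (f(lo) > 0 || f(hi) < 0) stop("prevalence K unattainable under the logistic model")
      alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
      if (abs(f(alpha)) > 1e-4) stop("intercept bisection failed to reach prevalence tolerance")
    }
    p <- stats::plogis(alpha + gs$score)
    status <- stats::rbinom(length(p), 1, p)
    truth <- list(model = "logistic", K = K, alpha = alpha,
                  beta = panel$beta, p_case = p)
  } else {
    h2 <- config$h2_liability
    gstd <- if (gs$sd > 0) gs$score / gs$sd else rep(0, length(gs$score))
    liab <- sqrt(h2) * gstd + sqrt(1 - h2) * stats::rnorm(length(gstd))
    status <- as.integer(liab > stats::qnorm(1 - K))
    truth <- list(model = "liability_threshold", K = K, h2 = h2,
                  beta = panel$beta, liability = liab, genetic_std = gstd)
  }
  list(status = status, truth = truth)
}

#' Simulate sibling genotypes by Mendelian transmission
#'
#' For each proband, each of the two parental transmissions to a sibling is
#' the proband's transmitted allele with probability 1/2 and otherwise a
#' fresh population allele (the untransmitted parental allele under random
#' mating at the population allele frequency). Expected sibling-proband
#' dosage correlation is 0.5 per variant.
#'
#' @param genotypes Proband dosage matrix (0/1/2 hard calls).
#' @param panel Panel tibble (allele frequencies).
#' @param seed Integer seed.
#' @return Sibling dosage matrix, same shape as `genotypes`.
#' @export
simulate_sibling_genotypes <- function(genotypes, panel, seed) {
  set.seed(seed)
  n <- nrow(genotypes); m <- ncol(genotypes)
  eaf <- matrix(panel$eaf, nrow = n, ncol = m, byrow = TRUE)
  # proband's two alleles: for dosage 1 assign the risk allele to one parent
  a1 <- matrix(0, n, m); a2 <- matrix(0, n, m)
  a1[genotypes >= 1] <- 1
  a2[genotypes == 2] <- 1
  share1 <- matrix(stats::runif(n * m) < 0.5, n, m)
  share2 <- matrix(stats::runif(n * m) < 0.5, n, m)
  fresh1 <- matrix(stats::rbinom(n * m, 1, eaf), n, m)
  fresh2 <- matrix(stats::rbinom(n * m, 1, eaf), n, m)
  sib <- ifelse(share1, a1, fresh1) + ifelse(share2, a2, fresh2)
  dimnames(sib) <- dimnames(genotypes)
  sib
}

#' Ascertain familial cases via an affected sibling
#'
#' Emulates recruitment of familial cases: each case proband gets one
#' simulated sibling (Mendelian transmission) whose status is drawn from the
#' same disease model; probands with an affected sibling are retained as
#' "familial". Under a heritable score this enriches retained probands for
#' high scores.
#'
#' @param genotypes Population dosage matrix.
#' @param status Population status vector (from [assign_status()]).
#' @param panel Panel tibble.
#' @param config [sim_config()] object.
#' @param seed Integer seed.
#' @param alpha Optional fixed logistic intercept (see [assign_status()]).
#' @return List: `familial_idx` (row indices of retained probands),
#'   `case_idx` (all case rows), `sib_status` (for cases).
#' @export
ascertain_familial <- function(genotypes, status, panel, config, seed, alpha = NULL) {
  case_idx <- which(status == 1)
  if (length(case_idx) == 0) {
    return(list(familial_idx = integer(0), case_idx = case_idx, sib_status = integer(0)))
  }
  sib_g <- simulate_sibling_genotypes(genotypes[case_idx, , drop = FALSE], panel, seed = seed + 1L)
  sib <- assign_status(sib_g, panel, config, seed = seed + 2L, alpha = alpha)
  list(familial_idx = case_idx[sib$status == 1],
       case_idx = case_idx,
       sib_status = sib$status)
}

#' Mask genotypes missing at random and attach imputation quality
#'
#' @param genotypes Dosage matrix.
#' @param panel Panel tibble (its `imputation_r2`/`genotyped` columns already
#'   describe quality; returned unchanged).
#' @param missing_rate Independent masking probability in \[0, 1).
#' @param seed Integer seed.
#' @return List: `genotypes` (with `NA`s), `panel`.
#' @export
apply_missingness <- function(genotypes, panel, missing_rate, seed) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate > 0) {
    set.seed(seed)
    mask <- matrix(stats::runif(length(genotypes)) < missing_rate,
                   nrow(genotypes), ncol(genotypes))
    genotypes[mask] <- NA_real_
  }
  list(genotypes = genotypes, panel = panel)
}

#' Simulate a discovery-GWAS effect estimate with selection
#'
#' `beta_hat ~ Normal(beta_true, se^2)`; the variant is "selected" when
#' `|beta_hat|/se` exceeds the two-sided significance threshold. Replicated
#' draws reproduce the winner's curse: among selected draws the mean
#' estimate overshoots the truth.
#'
#' @param beta_true True log-OR (scalar).
#' @param se Standard error.
#' @param alpha Two-sided selection level (default genome-wide 5e-8).
#' @param n_rep Number of replicate draws.
#' @param seed Integer seed.
#' @return Tibble: `beta_hat`, `selected`.
#' @export
simulate_discovery <- function(beta_true, se, alpha = 5e-8, n_rep = 1, seed) {
  stopifnot(se > 0)
  set.seed(seed)
  bh <- stats::rnorm(n_rep, beta_true, se)
  cthr <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(beta_hat = bh, selected = abs(bh) / se > cthr)
}

#' Simulate a full study-like cohort
#'
#' Generates the three inputs the pipeline consumes — variant panel,
#' genotype dosages and cohort phenotype table — with the statistical
#' structure the analysis assumes: a population under the configured disease
#' model, familial cases ascertained by affected sibling (optional),
#' sporadic cases and controls sampled from the remaining cases and
#' non-cases, group-specific ages and sexes, clinical flags at group rates,
#' missing genotypes, and per-variant imputation quality. Serrated-polyposis
#' individuals are sampled from the non-case pool (their score distribution
#' matches controls, the null the study observed for that group).
#'
#' @param config [sim_config()] object.
#' @return List of class `crcprs_sim_cohort`: `panel`, `genotypes` (with
#'   missingness), `cohort`, `truth`.
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_panel(config)
  g <- simulate_genotypes(panel, config$n_population, seed = config$seed + 1L)
  st <- assign_status(g, panel, config, seed = config$seed + 2L)
  status <- st$status

  sizes <- config$group_sizes
  case_idx <- which(status == 1)
  noncase_idx <- which(status == 0)
  if (config$familial_rule == "affected_sib") {
    fam <- ascertain_familial(g, status, panel, config, seed = config$seed + 3L,
                              alpha = st$truth$alpha)
    fam_pool <- fam$familial_idx
  } else {
    fam_pool <- case_idx
  }
  set.seed(config$seed + 4L)
  need <- function(pool, k, what) {
    if (length(pool) < k) stop("population too small: only ", length(pool), " ", what,
                               " available for a group of ", k)
    sample(pool, k)
  }
  fcrc_idx <- need(fam_pool, sizes[["fcrc"]], "familial cases")
  sporadic_pool <- setdiff(case_idx, fcrc_idx)
  sporadic_idx <- need(sporadic_pool, sizes[["sporadic_crc"]], "sporadic cases")
  control_idx <- need(noncase_idx, sizes[["control"]], "controls")
  sp_pool <- setdiff(noncase_idx, control_idx)
  sp_idx <- need(sp_pool, sizes[["sp"]], "SP individuals")

  idx <- c(fcrc_idx, sp_idx, sporadic_idx, control_idx)
  group <- rep(c("fcrc", "sp", "sporadic_crc", "control"),
               times = c(length(fcrc_idx), length(sp_idx), length(sporadic_idx), length(control_idx)))
  asm <- config$age_sex_model
  pars <- asm[match(group, asm$group), ]
  nn <- length(idx)
  cohort <- tibble::tibble(
    group = group,
    age = round(stats::rnorm(nn, pars$age_mean, pars$age_sd), 1),
    sex = ifelse(stats::runif(nn) < pars$male_frac, "male", "female"),
    fam_history_crc = ifelse(stats::runif(nn) < pars$fam_history_crc_rate, "yes", "no"),
    multiple_crc = stats::runif(nn) < pars$multiple_crc_rate
  )
  cohort$individual_id <- rownames(g)[idx]
  cohort$crc_affected <- cohort$group %in% c("fcrc", "sporadic_crc")
  cohort$age_at_dx <- ifelse(cohort$crc_affected, pmax(cohort$age, 18), NA_real_)
  cohort$multiple_any <- cohort$multiple_crc
  cohort$fam_history_any <- cohort$fam_history_crc
  cohort$criteria <- ifelse(cohort$group == "fcrc",
                            ifelse(stats::runif(nrow(cohort)) < 0.134, "amsterdam", "bethesda"),
                            "none")
  cohort$deceased <- ifelse(stats::runif(nrow(cohort)) < 0.08, "deceased", "alive")
  if (config$familial_rule == "affected_sib") {
    cohort$fam_history_crc[cohort$group == "fcrc"] <- "yes"
  }
  cohort <- dplyr::relocate(cohort, individual_id)

  geno <- g[idx, , drop = FALSE]
  masked <- apply_missingness(geno, panel, config$missing_rate, seed = config$seed + 5L)
  truth <- st$truth
  truth$population_status <- status
  truth$sampled_idx <- idx
  structure(list(panel = panel, genotypes = masked$genotypes,
                 cohort = validate_cohort(cohort), truth = truth,
                 config = config),
            class = "crcprs_sim_cohort")
}

#' Write a simulated cohort to the pipeline's input formats
#'
#' @param sim A `crcprs_sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (`panel`, `dosages`, `cohort`,
#'   `truth`), invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel_path <- file.path(dir, "panel.tsv")
  p <- sim$panel
  p$imputation_r2 <- ifelse(p$genotyped, "genotyped", sprintf("%.17g", p$imputation_r2))
  readr::write_tsv(p[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                         "beta", "eaf", "imputation_r2")], panel_path, progress = FALSE)
  dosage_path <- file.path(dir, "dosages.tsv")
  write_dosage_matrix(sim$genotypes, dosage_path)
  cohort_path <- file.path(dir, "cohort.tsv")
  readr::write_tsv(sim$cohort, cohort_path, progress = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(model = sim$truth$model, K = sim$truth$K,
                            h2 = sim$truth$h2, beta = sim$truth$beta),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(panel = panel_path, dosages = dosage_path,
                 cohort = cohort_path, truth = truth_path))
}
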