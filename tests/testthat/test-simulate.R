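test_that("simulated panel matches its configuration and is deterministic", {
  cfg <- sim_config(n_variants = 92, seed = 5)
  p1 <- simulate_panel(cfg)
  expect_equal(nrow(p1), 92)
  expect_true(all(p1$beta > 0))
  expect_true(all(p1$eaf >= cfg$maf_range[1] & p1$eaf <= cfg$maf_range[2]))
  expect_true(all(p1$imputation_r2[!p1$genotyped] > 0))
  expect_identical(simulate_panel(cfg), p1)

  deg <- simulate_panel(sim_config(n_variants = 10, maf_range = c(0.3, 0.3), seed = 2))
  expect_equal(deg$eaf, rep(0.3, 10))

  # a 95-variant panel with 3 low-quality imputed variants filters to 92
  cfg95 <- sim_config(n_variants = 95, n_low_r2 = 3, seed = 9)
  filtered <- filter_by_imputation_r2(simulate_panel(cfg95), 0.3)
  expect_equal(sum(filtered$included), 92)
})

test_that("genotype dosages follow binomial sampling under Hardy-Weinberg", {
  cfg <- sim_config(n_variants = 5, seed = 3)
  panel <- simulate_panel(cfg)
  panel$eaf <- c(0, 0.5, 0.5, 0.2, 0.8)
  g <- simulate_genotypes(panel, 10000, seed = 4)
  expect_true(all(g[, 1] == 0))
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(g[, 2]) - 1), 3 * se)

  # HWE genotype frequencies across a larger panel
  panel2 <- simulate_panel(sim_config(n_variants = 60, seed = 6))
  g2 <- simulate_genotypes(panel2, 4000, seed = 7)
  hwe_p <- vapply(seq_len(60), function(j) {
    counts <- tabulate(g2[, j] + 1, 3)
    p <- panel2$eaf[j]
    expected <- 4000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum((counts - expected)^2 / expected)
  }, numeric(1))
  expect_gte(mean(hwe_p < qchisq(0.999, df = 2)), 0.95)
})

test_that("status assignment hits the target prevalence and recovers effects", {
  cfg0 <- sim_config(n_variants = 8, effect_model = "fixed", fixed_logor = 0,
                     prevalence_K = 0.1, disease_model = "logistic", seed = 13)
  panel0 <- simulate_panel(cfg0)
  panel0$beta <- rep(0, 8)
  g0 <- simulate_genotypes(panel0, 20000, seed = 14)
  st0 <- assign_status(g0, panel0, cfg0, seed = 15)
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(mean(st0$status) - 0.1), 3 * se)

  # logistic model: per-allele ORs recovered by logistic regression
  cfg1 <- sim_config(n_variants = 5, effect_model = "fixed", fixed_logor = log(1.3),
                     prevalence_K = 0.15, disease_model = "logistic", seed = 16)
  panel1 <- simulate_panel(cfg1)
  g1 <- simulate_genotypes(panel1, 50000, seed = 17)
  st1 <- assign_status(g1, panel1, cfg1, seed = 18)
  d <- tibble::as_tibble(as.data.frame(g1))
  names(d) <- paste0("v", 1:5)
  d$case <- st1$status
  fit <- fit_logistic(d, "case", paste0("v", 1:5))
  est <- fit$coefficients[-1, ]
  expect_true(all(abs(est$estimate - log(1.3)) < 3 * est$std_error))

  # null liability model: score has no discrimination
  cfg2 <- sim_config(n_variants = 8, h2_liability = 0, prevalence_K = 0.2, seed = 19)
  panel2 <- simulate_panel(cfg2)
  g2 <- simulate_genotypes(panel2, 10000, seed = 20)
  st2 <- assign_status(g2, panel2, cfg2, seed = 21)
  prs <- drop(g2 %*% panel2$beta)
  expect_lt(abs(auc(prs, st2$status) - 0.5), 3 * 0.6 / sqrt(sum(st2$status)))
})

test_that("sibling genotypes show the expected kinship correlation", {
  cfg <- sim_config(n_variants = 30, seed = 23)
  panel <- simulate_panel(cfg)
  g <- simulate_genotypes(panel, 4000, seed = 24)
  sib <- simulate_sibling_genotypes(g, panel, seed = 25)
  cors <- vapply(seq_len(30), function(j) cor(g[, j], sib[, j]), numeric(1))
  se <- 1 / sqrt(4000)  # approximate SE of r near 0.5
  expect_true(all(abs(cors - 0.5) < 4 * se))
  expect_lt(abs(mean(cors) - 0.5), 3 * se / sqrt(30))
  expect_true(all(sib %in% 0:2))
})

test_that("familial ascertainment is null when the score carries no risk", {
  cfg <- sim_config(n_variants = 10, h2_liability = 0, prevalence_K = 0.2, seed = 26)
  panel <- simulate_panel(cfg)
  g <- simulate_genotypes(panel, 20000, seed = 27)
  st <- assign_status(g, panel, cfg, seed = 28)
  fam <- ascertain_familial(g, st$status, panel, cfg, seed = 29)
  # sibling of a case is a case with probability ~K when nothing is heritable
  retention <- length(fam$familial_idx) / length(fam$case_idx)
  se <- sqrt(0.2 * 0.8 / length(fam$case_idx))
  expect_lt(abs(retention - 0.2), 3 * se)
})

test_that("familial ascertainment enriches the score when it is heritable", {
  cfg <- sim_config(n_variants = 50, h2_liability = 0.2, prevalence_K = 0.04, seed = 31)
  panel <- simulate_panel(cfg)
  g <- simulate_genotypes(panel, 20000, seed = 32)
  st <- assign_status(g, panel, cfg, seed = 33)
  fam <- ascertain_familial(g, st$status, panel, cfg, seed = 34)
  prs <- drop(g %*% panel$beta)
  expect_gt(mean(prs[fam$familial_idx]), mean(prs[fam$case_idx]))
})

test_that("missingness masking is calibrated and identity at rate zero", {
  cfg <- sim_config(n_variants = 92, seed = 36)
  panel <- simulate_panel(cfg)
  g <- simulate_genotypes(panel, 1000, seed = 37)
  expect_identical(apply_missingness(g, panel, 0, seed = 38)$genotypes, g)
  masked <- apply_missingness(g, panel, 0.1, seed = 39)$genotypes
  frac <- mean(is.na(masked))
  se <- sqrt(0.1 * 0.9 / length(g))
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("discovery simulation reproduces selection and the winner's curse", {
  se <- 0.02
  alpha <- 5e-4
  cthr <- qnorm(1 - alpha / 2)

  # far above threshold: always selected
  far <- simulate_discovery(10 * cthr * se, se, alpha, n_rep = 500, seed = 41)
  expect_true(all(far$selected))

  # null effect: selection fraction ~ alpha
  null <- simulate_discovery(0, se, alpha, n_rep = 200000, seed = 42)
  se_bin <- sqrt(alpha * (1 - alpha) / nrow(null))
  expect_lt(abs(mean(null$selected) - alpha), 3 * se_bin)

  # near-threshold true effect: selected estimates overshoot, correction helps
  beta_true <- cthr * se
  disc <- simulate_discovery(beta_true, se, alpha, n_rep = 10000, seed = 43)
  sel <- disc$beta_hat[disc$selected]
  naive_bias <- mean(sel) - beta_true
  expect_gt(naive_bias, 0)
  corrected <- winners_curse_correct(sel, se, alpha)
  expect_lt(abs(mean(corrected) - beta_true), abs(naive_bias))
})

test_that("the full simulated cohort is deterministic and structurally valid", {
  cfg <- sim_config(n_population = 30000,
                    group_sizes = c(fcrc = 40, sp = 20, sporadic_crc = 150, control = 400),
                    h2_liability = 0.2, seed = 44)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$genotypes, sim2$genotypes)
  expect_identical(sim1$cohort, sim2$cohort)
  expect_identical(sim1$panel, sim2$panel)

  expect_equal(as.integer(table(sim1$cohort$group)[c("fcrc", "sp", "sporadic_crc", "control")]),
               c(40, 20, 150, 400))
  expect_true(all(sim1$genotypes >= 0 & sim1$genotypes <= 2, na.rm = TRUE))
  # written files reproduce byte-identically under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_sim_cohort(sim1, d1); f2 <- write_sim_cohort(sim2, d2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
})
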