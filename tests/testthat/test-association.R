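test_that("Welch t-test: identity case and agreement with a permutation oracle", {
  x <- c(1, 2, 3)
  expect_equal(welch_t_test(x, x)$statistic, 0)
  expect_equal(welch_t_test(x, x)$p_value, 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")

  # at a moderate balanced sample size the Welch p agrees with a label
  # permutation oracle of the same statistic
  set.seed(404)
  a <- rnorm(30, 0.3); b <- rnorm(30)
  obs <- welch_t_test(a, b)
  pooled <- c(a, b); n <- 60; n1 <- 30
  welch_t <- function(xs, ys) {
    (mean(xs) - mean(ys)) / sqrt(var(xs) / length(xs) + var(ys) / length(ys))
  }
  nrep <- 40000
  perm <- vapply(seq_len(nrep), function(i) {
    idx <- sample.int(n, n1)
    abs(welch_t(pooled[idx], pooled[-idx]))
  }, numeric(1))
  p_perm <- mean(perm >= abs(obs$statistic))
  expect_lt(abs(p_perm - obs$p_value), 0.01)
})

test_that("Welch p-values are uniform under the null", {
  set.seed(77)
  ps <- vapply(seq_len(400), function(i) {
    welch_t_test(rnorm(40), rnorm(40))$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Pearson chi-squared reproduces published contingency p-values at 4 dp", {
  cases <- list(
    list(tab = rbind(c(94, 64), c(94, 33)), p = 0.0101),
    list(tab = rbind(c(90, 64), c(53, 71)), p = 0.0092),
    list(tab = rbind(c(91, 67), c(76, 51)), p = 0.7018),
    list(tab = rbind(c(19, 139), c(6, 121)), p = 0.0303)
  )
  for (cs in cases) {
    expect_equal(round(pearson_chi2(cs$tab)$p_value, 4), cs$p)
  }
  # independence gives chi2 = 0, p = 1
  flat <- pearson_chi2(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
  # invariant to transposition and to swapping both row and column labels
  t1 <- rbind(c(12, 5), c(7, 21))
  expect_equal(pearson_chi2(t1)$chi2, pearson_chi2(t(t1))$chi2)
  expect_equal(pearson_chi2(t1)$chi2, pearson_chi2(t1[2:1, 2:1])$chi2)
  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("crude OR: cross-product arithmetic, Woolf CI and reciprocal symmetry", {
  expect_equal(round(crude_or(rbind(c(90, 64), c(53, 71)))$or, 3), 1.884)
  expect_equal(round(crude_or(rbind(c(19, 139), c(6, 121)))$or, 3), 2.757)
  expect_equal(crude_or(rbind(c(1, 1), c(1, 1)))$or, 1)
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 40) + 1, 2, 2)
    expect_lt(abs(crude_or(tab)$or * crude_or(tab[2:1, ])$or - 1), 1e-12)
  }
  expect_error(crude_or(rbind(c(0, 5), c(3, 4))), "zero cell")
  expect_equal(crude_or(rbind(c(0, 5), c(3, 4)), haldane = TRUE)$or,
               (0.5 * 4.5) / (5.5 * 3.5))
})

test_that("logistic coefficient on a 2x2 equals the log crude OR", {
  d <- table_to_individuals(90, 64, 53, 71)
  fit <- fit_logistic(d, "case", "exposed")
  expect_lt(abs(exp(fit$coefficients$estimate[2]) -
                  crude_or(rbind(c(90, 53), c(64, 71)))$or), 1e-6)
})

test_that("logistic fit errors on degenerate designs and separation", {
  d <- table_to_individuals(20, 20, 20, 20)
  d$zero <- 0
  expect_error(fit_logistic(d, "case", c("exposed", "zero")), "rank-deficient")
  sep <- tibble::tibble(case = rep(c(0, 1), each = 20),
                        x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(fit_logistic(sep, "case", "x"), "separation")
  expect_error(fit_logistic(tibble::tibble(case = rep(1, 10), x = rnorm(10)), "case", "x"),
               "single class")
})

test_that("logistic log-likelihood is the optimum over a surrounding grid", {
  set.seed(12)
  d <- tibble::tibble(x = rnorm(40))
  d$case <- rbinom(40, 1, plogis(0.3 + 0.8 * d$x))
  fit <- fit_logistic(d, "case", "x")
  b <- fit$coefficients$estimate
  ll <- function(b0, b1) sum(dbinom(d$case, 1, plogis(b0 + b1 * d$x), log = TRUE))
  grid <- expand.grid(b0 = b[1] + seq(-1, 1, length.out = 15),
                      b1 = b[2] + seq(-1, 1, length.out = 15))
  grid_ll <- mapply(ll, grid$b0, grid$b1)
  expect_gte(fit$log_likelihood + 1e-8, max(grid_ll))
})

test_that("null logistic Wald p-values have nominal size", {
  set.seed(55)
  rejections <- vapply(seq_len(200), function(i) {
    d <- tibble::tibble(x = rnorm(500), age = rnorm(500), case = rbinom(500, 1, 0.4))
    fit_logistic(d, "case", c("x", "age"))$coefficients$p_value[2] < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.90)
  expect_lte(mean(!rejections), 0.99)
})

test_that("quantile OR profile: reference fixed at 1, crude equivalence, null flatness", {
  set.seed(31)
  n <- 800
  scored <- tibble::tibble(
    individual_id = sprintf("i%04d", 1:n),
    group = rep(c("fcrc", "control"), each = n / 2),
    wprs = runif(n), age = rnorm(n, 60, 10),
    sex = sample(c("male", "female"), n, TRUE),
    complete = TRUE
  )
  scored$quantile <- assign_quantiles(scored$wprs, 10)
  prof <- quantile_or_profile(scored, covariates = c("age", "sex"), reference_q = 5)
  expect_equal(prof$or[prof$quantile == 5], 1)
  expect_true(prof$reference[prof$quantile == 5])
  # null composition: every CI covers 1
  nonref <- prof[!prof$reference & !is.na(prof$or), ]
  expect_true(all(nonref$ci_low <= 1 & nonref$ci_high >= 1))

  # with no covariates the OR equals the crude 2x2 cross-product
  prof0 <- quantile_or_profile(scored, covariates = character(0), reference_q = 5)
  q <- 8
  nq <- scored[scored$quantile == q, ]; ref <- scored[scored$quantile == 5, ]
  tab <- rbind(c(sum(nq$group == "fcrc"), sum(nq$group == "control")),
               c(sum(ref$group == "fcrc"), sum(ref$group == "control")))
  expect_lt(abs(prof0$or[prof0$quantile == q] - crude_or(rbind(tab[1, ], tab[2, ]))$or), 1e-6)
})

test_that("quantile OR profile rises with a positive score effect", {
  set.seed(91)
  hits <- vapply(seq_len(20), function(i) {
    n <- 1500
    score <- rnorm(n)
    case <- rbinom(n, 1, plogis(-1.2 + 0.6 * score))
    scored <- tibble::tibble(
      individual_id = sprintf("i%04d", 1:n),
      group = ifelse(case == 1, "fcrc", "control"),
      wprs = score, age = rnorm(n, 60, 5),
      sex = sample(c("male", "female"), n, TRUE), complete = TRUE
    )
    scored$quantile <- assign_quantiles(scored$wprs, 10)
    prof <- quantile_or_profile(scored, covariates = character(0), reference_q = 5)
    ok <- !is.na(prof$or)
    cor(prof$or[ok], prof$quantile[ok], method = "spearman") > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("interaction test: errors on degenerate modifiers, detects a real product term", {
  set.seed(101)
  d <- tibble::tibble(wprs = rnorm(300), mod = rbinom(300, 1, 0.5),
                      age = rnorm(300), sex = sample(c("male", "female"), 300, TRUE))
  d$case <- rbinom(300, 1, plogis(0.2 * d$wprs))
  expect_error(interaction_test(dplyr::mutate(d, mod = 1), "case", "wprs", "mod"),
               "two observed levels")
  # modifier duplicated as covariate is rank-deficient
  expect_error(interaction_test(d, "case", "wprs", "mod", covariates = c("age", "mod")),
               "rank-deficient")

  # strong interaction recovered
  set.seed(202)
  hits <- vapply(seq_len(40), function(i) {
    n <- 2000
    dd <- tibble::tibble(wprs = rnorm(n), mod = rbinom(n, 1, 0.5),
                         age = rnorm(n), sex = sample(c("male", "female"), n, TRUE))
    dd$case <- rbinom(n, 1, plogis(-0.5 + 0.1 * dd$wprs + 0.5 * dd$wprs * dd$mod))
    interaction_test(dd, "case", "wprs", "mod")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("interaction p-values are uniform under the null", {
  set.seed(303)
  ps <- vapply(seq_len(200), function(i) {
    n <- 400
    dd <- tibble::tibble(wprs = rnorm(n), mod = rbinom(n, 1, 0.5),
                         age = rnorm(n), sex = sample(c("male", "female"), n, TRUE))
    dd$case <- rbinom(n, 1, plogis(0.2 * dd$wprs - 0.3))
    interaction_test(dd, "case", "wprs", "mod")$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
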