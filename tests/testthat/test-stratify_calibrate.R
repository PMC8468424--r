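test_that("stratified OR table reproduces published decile estimates from counts", {
  fx <- make_fixture("published_deciles")
  tab <- stratified_or_table(fx$decile, fx$status, ref_bin = 5)
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$is_reference), 1L)
  expect_equal(tab$or[tab$bin == 5], 1)
  printed <- c(0.36, 0.48, 0.75, 1.18, NA, 1.19, 1.46, 2.5, 3.22, 4.58)
  expect_equal(round_half_up(tab$or[tab$bin != 5], 2), printed[-5])
  # hand-check of one row: (122*94)/(62*74)
  expect_equal(tab$or[tab$bin == 8], (122 * 94) / (62 * 74),
               tolerance = 1e-12)
  expect_equal(sum(tab$pct_controls), 100, tolerance = 1e-9)
  expect_equal(sum(tab$pct_cases), 100, tolerance = 1e-9)
})

test_that("equal case:control ratios give OR 1 and one-status bins are flagged", {
  bins <- rep(c(1, 2, 3), c(40, 40, 10))
  y <- c(rep(c(0, 1), 20), rep(c(0, 1), 20), rep(0, 10))
  tab <- stratified_or_table(bins, y, ref_bin = 1)
  expect_equal(tab$or[tab$bin == 2], 1)
  expect_false(tab$estimable[tab$bin == 3])
  expect_true(is.na(tab$or[tab$bin == 3]))
  expect_error(stratified_or_table(bins, rep(0, length(y)), 1),
               "reference bin")
})

test_that("Hosmer-Lemeshow matches a hand-expanded toy and the printed pair", {
  # one group, constant p equal to the observed rate: chi2 exactly 0
  hl0 <- hosmer_lemeshow(rep(0.5, 10), rep(c(0, 1), 5), n_groups = 1)
  expect_equal(hl0$chi2, 0)

  # 6 observations, 2 groups of 3, O/E per cell expanded by hand
  p <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8)
  y <- c(0, 0, 1, 1, 0, 1)
  hl <- hosmer_lemeshow(p, y, n_groups = 2)
  e1 <- 0.1 + 0.2 + 0.3; o1 <- 1
  e2 <- 0.6 + 0.7 + 0.8; o2 <- 2
  hand <- (o1 - e1)^2 / e1 + ((3 - o1) - (3 - e1))^2 / (3 - e1) +
    (o2 - e2)^2 / e2 + ((3 - o2) - (3 - e2))^2 / (3 - e2)
  expect_equal(hl$chi2, hand, tolerance = 1e-12)
  expect_equal(hl$df, 0L)
  expect_equal(sum(hl$groups$expected), sum(p), tolerance = 1e-6)

  # the printed chi-square/p pair at 10 groups (df 8)
  expect_equal(round(pchisq(11.77, 8, lower.tail = FALSE), 3), 0.162)
})

test_that("Hosmer-Lemeshow keeps tied probabilities in one group", {
  set.seed(60)
  p <- c(rep(0.2, 6), rep(0.4, 2), rep(0.7, 4))
  y <- rbinom(12, 1, p)
  hl <- hosmer_lemeshow(p, y, n_groups = 4)
  # tied p-values never straddle groups: the first boundary extends past
  # the run of 0.2s, the third past the run of 0.7s
  for (g in seq_len(nrow(hl$groups))) {
    lo <- cumsum(c(0, hl$groups$n))[g] + 1
    hi <- cumsum(hl$groups$n)[g]
    if (hi < 12) expect_true(sort(p)[hi] != sort(p)[hi + 1])
  }
  expect_equal(hl$groups$n, c(6L, 6L))
  expect_error(hosmer_lemeshow(c(0, 0.5, 0.7), c(0, 1, 0), 1), "strictly")
})

test_that("AUC follows the Mann-Whitney/tie conventions", {
  expect_equal(auc_delong(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auc_delong(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  r <- auc_delong(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_bruteforce(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_error(auc_delong(1:4, rep(1, 4)), "both")
})

test_that("AUC equals brute-force pair counting on random tied instances", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_delong(scores, y)$auc, auc_bruteforce(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  scores <- c(rnorm(80), rnorm(60, 1))
  y <- rep(c(0, 1), c(80, 60))
  ours <- auc_delong(scores, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, scores, quiet = TRUE),
                                       method = "delong"))
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("sensitivity and specificity count threshold crossings", {
  expect_equal(sens_spec(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sens_spec(rep(0.6, 6), rep(c(1, 0), 3)),
               c(sensitivity = 1, specificity = 0))
  expect_equal(sens_spec(c(0.7, 0.3, 0.6, 0.1), c(1, 1, 0, 0)),
               c(sensitivity = 0.5, specificity = 0.5))
  expect_error(sens_spec(c(0.2, 0.8), c(1, 1)), "both")
})

test_that("integrated model recovers generating coefficients", {
  sim <- simulate_cohort(simulation_spec(n_cases = 1109, n_controls = 1177,
                                         seed = 63))
  w <- prs_weights(load_panel())
  prs <- compute_prs(sim$genotypes, w)
  m <- integrated_model(sim$cohort, prs)
  expect_true(m$fit$converged)

  cs <- default_covariate_spec()
  truth <- c(prs = 1,
             menopausal = cs$menopausal$beta,
             age_menarche = cs$age_menarche$beta,
             parous = cs$parous$beta,
             fftp_cat1 = cs$age_fftp_cat$betas[2],
             fftp_cat2 = cs$age_fftp_cat$betas[3],
             fftp_cat3 = cs$age_fftp_cat$betas[4],
             fftp_cat4 = cs$age_fftp_cat$betas[5],
             breastfed = cs$breastfed$beta,
             height_cm = cs$height_cm$beta,
             bmi = cs$bmi$beta,
             hrt = cs$hrt$beta,
             smoker = cs$smoker$beta,
             family_history = cs$family_history$beta)
  est <- m$fit$coefficients[names(truth)]
  se <- m$fit$standard_errors[names(truth)]
  within <- abs(est - truth) <= 3 * se
  expect_gte(sum(within), ceiling(length(truth) * 10 / 11))
})

test_that("integrated model decile table conserves percentages and bins everyone", {
  sim <- small_simulated(200, 220, seed = 64)
  w <- prs_weights(load_panel())
  prs <- compute_prs(sim$genotypes, w)
  m <- integrated_model(sim$cohort, prs)
  expect_equal(length(m$bins), nrow(sim$cohort))
  expect_true(all(m$bins %in% 1:10))
  expect_equal(sum(m$strata$pct_controls), 100, tolerance = 1e-9)
  expect_equal(sum(m$strata$pct_cases), 100, tolerance = 1e-9)
  occ <- table(factor(m$bins, levels = 1:10))
  expect_lte(max(occ) - min(occ), 1)
})

test_that("null integrated model has chance-level discrimination", {
  null_cov <- default_covariate_spec()
  for (nm in names(null_cov)) {
    if (null_cov[[nm]]$type == "ordinal") null_cov[[nm]]$betas[] <- 0
    else null_cov[[nm]]$beta <- 0
  }
  w <- prs_weights(load_panel())
  # the null property is evaluated out-of-sample: the apparent AUC of a
  # 14-term model carries upward optimism even when every effect is zero,
  # so coefficients fitted on one cohort score an independent one
  aucs <- numeric(20)
  for (s in seq_along(aucs)) {
    null_spec <- function(seed) simulation_spec(
      n_cases = 1000, n_controls = 1000, seed = seed,
      snp_betas = rep(0, 15), covariate_spec = null_cov, intercept = 0)
    train <- simulate_cohort(null_spec(400 + s))
    test <- simulate_cohort(null_spec(800 + s))
    m <- integrated_model(train$cohort,
                          compute_prs(train$genotypes, w))
    design_test <- integrated_design(test$cohort,
                                     compute_prs(test$genotypes, w))
    p_test <- plogis(design_test[, names(m$fit$coefficients)] %*%
                       m$fit$coefficients)
    aucs[s] <- auc_delong(as.numeric(p_test), test$cohort$status)$auc
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
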