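# direct null/effect generators for the regression models: dosage built from
# a het-deletion at a given carrier frequency, metabolites standard normal
null_draw <- function(n, n_met = 1, freq = 0.3, n_cov = 3) {
  dosage <- 2 - rbinom(n, 1, freq) + rnorm(n, sd = 0.05)
  met <- matrix(rnorm(n * n_met), n, n_met,
                dimnames = list(NULL, sprintf("met_%03d", seq_len(n_met))))
  covs <- cbind(matrix(rnorm(n * n_cov), n,
                       dimnames = list(NULL, paste0("PC", seq_len(n_cov)))),
                sex_male = rbinom(n, 1, 0.5))
  list(dosage = dosage, met = met, covs = covs)
}

test_that("univariate reverse regression is calibrated and finds planted effects", {
  set.seed(101)
  hits <- vapply(1:400, function(i) {
    d <- null_draw(200)
    univariate_assoc(d$dosage, d$met, d$covs, m_effective = 1)$p_raw < 0.05
  }, NA)
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.08)

  # strong planted effect: tiny p with the matching sign
  set.seed(102)
  d <- null_draw(500)
  met <- d$met
  met[, 1] <- met[, 1] + 2 * (d$dosage - 2)
  rec <- univariate_assoc(d$dosage, met, d$covs, m_effective = 1)
  expect_lt(rec$p_raw, 1e-6)
  expect_gt(rec$beta, 0)
  expect_true(rec$reportable)
  expect_gte(rec$p_adjusted, rec$p_raw)

  # a metabolite duplicated as a covariate exercises the collinearity path
  covs_bad <- cbind(d$covs, dup = met[, 1])
  expect_warning(univariate_assoc(d$dosage, met, covs_bad, m_effective = 1),
                 "collinear")
})

test_that("reverse and forward regressions give the same t-test", {
  set.seed(103)
  d <- null_draw(300)
  met <- d$met
  met[, 1] <- met[, 1] + 0.3 * (d$dosage - 2)
  rec <- univariate_assoc(d$dosage, met, d$covs, m_effective = 1)
  fwd <- summary(lm(met[, 1] ~ d$dosage + d$covs))$coefficients[2, ]
  t_rev <- rec$beta / rec$se
  t_fwd <- fwd["Estimate"] / fwd["Std. Error"]
  expect_equal(unname(t_rev), unname(t_fwd), tolerance = 1e-9)
  expect_equal(rec$p_raw, unname(fwd[4]), tolerance = 1e-9)
})

test_that("LRR validation model mirrors the dosage model", {
  set.seed(104)
  d <- null_draw(400)
  met <- d$met
  met[, 1] <- met[, 1] + 0.8 * (d$dosage - 2)
  lrr <- -0.33 * (2 - d$dosage) + rnorm(400, sd = 0.05)  # tracks copy loss
  rd <- univariate_assoc(d$dosage, met, d$covs, m_effective = 1)
  rl <- lrr_assoc(lrr, met, d$covs, m_effective = 1)
  expect_identical(rl$model, "lrr")
  expect_true(is.na(rl$maf))
  expect_equal(sign(rl$beta), sign(rd$beta))

  # an affine transform of the outcome leaves the test invariant
  r2 <- lrr_assoc(3 * d$dosage - 1, met, d$covs, m_effective = 1)
  expect_equal(r2$p_raw, rd$p_raw, tolerance = 1e-9)
})

test_that("backward selection returns the planted metabolite signature", {
  set.seed(105)
  d <- null_draw(2000, n_met = 30)
  met <- d$met
  met[, 3] <- met[, 3] + 0.25 * (d$dosage - 2)
  met[, 17] <- met[, 17] + 0.25 * (d$dosage - 2)
  sig <- multivariate_signature(d$dosage, met, d$covs, m_effective = 1)
  expect_true(all(c("met_003", "met_017") %in% sig$selected_metabolites))
  expect_lt(sig$joint_p_raw, 1e-10)
  expect_named(sig$betas, sig$selected_metabolites)
  expect_lte(sig$n_iterations, 31L)

  # refitting the final joint model reproduces the joint p-value
  refit_p <- cnvmetabo:::joint_f_test(
    d$dosage, met[, sig$selected_metabolites, drop = FALSE], d$covs)
  expect_equal(refit_p, sig$joint_p_raw, tolerance = 1e-12)

  # null panel: signatures are empty or near-empty on most seeds
  set.seed(106)
  sizes <- vapply(1:20, function(i) {
    d0 <- null_draw(300, n_met = 10)
    length(multivariate_signature(d0$dosage, d0$met, d0$covs,
                                  m_effective = 1)$selected_metabolites)
  }, 0L)
  expect_gt(mean(sizes <= 1), 0.6)

  # a single-metabolite panel reduces to the univariate test
  set.seed(107)
  d1 <- null_draw(300, n_met = 1)
  met1 <- d1$met
  met1[, 1] <- met1[, 1] + 0.5 * (d1$dosage - 2)
  sig1 <- multivariate_signature(d1$dosage, met1, d1$covs, m_effective = 1,
                                 drop_alpha = 1)
  uni1 <- univariate_assoc(d1$dosage, met1, d1$covs, m_effective = 1)
  expect_equal(sig1$joint_p_raw, uni1$p_raw, tolerance = 1e-9)

  # small n triggers the univariate pre-screen
  set.seed(108)
  d2 <- null_draw(30, n_met = 40)
  expect_warning(multivariate_signature(d2$dosage, d2$met, d2$covs,
                                        m_effective = 1), "pre-screened")
})

test_that("effective number of tests follows the eigenvalue-variance formula", {
  expect_equal(effective_tests(diag(10))$m_effective, 10)
  expect_equal(effective_tests(diag(10))$var_lambda, 0)

  for (m in c(3, 7, 20)) {
    ones <- matrix(1, m, m)
    expect_equal(effective_tests(ones)$m_effective, 1)
  }

  # random correlation matrices match a direct evaluation of the formula
  set.seed(109)
  for (i in 1:10) {
    X <- matrix(rnorm(200 * 5), 200, 5)
    C <- cor(X)
    et <- effective_tests(C)
    lambda <- eigen(C)$values
    expect_equal(et$var_lambda, var(lambda), tolerance = 1e-12)
    expect_equal(et$m_effective, 1 + 4 * (1 - var(lambda) / 5),
                 tolerance = 1e-12)
    expect_gte(et$m_effective, 1); expect_lte(et$m_effective, 5)
  }

  # m_effective shrinks as a pairwise correlation grows (3x3 grid)
  meff <- vapply(seq(0, 0.95, by = 0.05), function(r) {
    C <- diag(3); C[1, 2] <- C[2, 1] <- r
    effective_tests(C)$m_effective
  }, 0)
  expect_true(all(diff(meff) <= 1e-12))

  expect_error(effective_tests(matrix(c(1, 2, 2, 1), 2)), "positive semidefinite")
  expect_error(effective_tests(matrix(c(1, 0.1, 0.3, 1), 2)), "symmetric")
  expect_error(effective_tests(matrix(c(2, 0, 0, 2), 2)), "unit diagonal")
})

test_that("Sidak-style adjustment is exact, monotone and stable", {
  expect_equal(adjust_p(0.05, 1), 0.05)
  expect_gt(adjust_p(0.05, 2), adjust_p(0.05, 1))
  expect_equal(adjust_p(0.2, 3), 1 - (1 - 0.2)^3, tolerance = 1e-12)
  expect_equal(adjust_p(1e-300, 100), 100 * 1e-300, tolerance = 1e-6)
  expect_equal(adjust_p(1, 5), 1)
  expect_error(adjust_p(0, 5), "0, 1")
  expect_error(adjust_p(1.2, 5), "0, 1")
})

test_that("countAll stratification and Mann-Whitney validation", {
  sv <- stratified_validation(c(1.2, 2.0, 3.1), c(0, 0, 0))
  expect_equal(as.character(sv$labels), c("deletion", "neutral", "duplication"))
  expect_true(all(sv$tests$status == "skipped"))   # groups of size 1

  # null calibration: p roughly uniform over replicates
  set.seed(110)
  ps <- vapply(1:200, function(i) {
    ca <- c(runif(60, 1.0, 1.5), runif(60, 1.9, 2.1))
    stratified_validation(ca, rnorm(120))$tests$p[1]
  }, 0)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # shifted deletion-group phenotype: high power
  set.seed(111)
  hits <- vapply(1:50, function(i) {
    ca <- c(runif(200, 1.0, 1.5), runif(200, 1.9, 2.1))
    y <- c(rnorm(200, mean = 0.5), rnorm(200))
    stratified_validation(ca, y)$tests$p[1] < 0.01
  }, NA)
  expect_gte(mean(hits), 0.95)

  # all samples in one group: informative status, no test
  one <- stratified_validation(rep(2, 10), rnorm(10))
  expect_true(all(one$tests$status[one$tests$n_group == 0] == "skipped"))
})
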