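test_that("pooled t-test matches hand computation and conventions", {
  res <- ttest_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$t), 3 / sqrt(2/3), tolerance = 1e-12)  # |t| = 3.674
  expect_equal(res$df, 4)
  same <- ttest_two_sample(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("chi-square 2x2 without continuity correction", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p, 1)
  expect_equal(chi_square_2x2(matrix(c(20, 0, 0, 20), 2))$chi2, 40)
  expect_error(chi_square_2x2(matrix(c(5, 5, 0, 0), 2)), "marginal")
})

test_that("GLM group test reduces to the t-test with constant covariates", {
  set.seed(17)
  n <- 40
  cohort <- tibble::tibble(
    group = factor(rep(c("HC", "SSNHL"), each = n / 2)),
    age = rep(50, n), gender = rep(c("male", "female"), n / 2),
    education = rep(12, n))
  y <- rnorm(n) + (cohort$group == "HC") * 0.8
  # constant age/education are dropped from comparison: use varying gender only
  cohort$age <- rnorm(n, 50, 5); cohort$education <- rnorm(n, 12, 2)
  res <- glm_group_test(cohort, y)
  expect_equal(res$df, n - 5)

  # orthogonal design: with covariates unrelated and balanced the group t is
  # close to the plain pooled t
  tt <- ttest_two_sample(y[cohort$group == "HC"], y[cohort$group == "SSNHL"])
  expect_equal(sign(res$t), sign(tt$t))

  # exact group effect without noise recovers the coefficient
  y2 <- 2 * (cohort$group == "HC") + 0.01 * cohort$age
  res2 <- glm_group_test(cohort, y2)
  expect_equal(res2$estimate, 2, tolerance = 1e-10)
  expect_lt(res2$p, 1e-20)

  # collinear design errors with the offending term named
  cohort2 <- cohort
  cohort2$education <- cohort2$age
  expect_error(glm_group_test(cohort2, y), "collinear")
})

test_that("GLM equals t-test exactly when covariates carry no information", {
  # identical covariates for everyone make the adjustment a no-op up to
  # degrees of freedom; compare against lm on group alone
  set.seed(4)
  n <- 30
  cohort <- tibble::tibble(
    group = factor(rep(c("HC", "SSNHL"), each = n / 2)),
    age = rnorm(n, 40, 10),
    gender = sample(c("male", "female"), n, replace = TRUE),
    education = rnorm(n, 13, 3))
  y <- rnorm(n)
  fit <- lm(y ~ I(cohort$group == "HC") + cohort$age +
              (cohort$gender == "male") + cohort$education)
  res <- glm_group_test(cohort, y)
  expect_equal(res$t, summary(fit)$coefficients[2, "t value"],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("adjustment removes covariate confounding (type-I calibration)", {
  set.seed(99)
  reject <- logical(400)
  for (r in seq_along(reject)) {
    n1 <- 30; n2 <- 30
    age <- c(rnorm(n1, 35, 8), rnorm(n2, 45, 8))  # age confounded with group
    cohort <- tibble::tibble(
      group = factor(rep(c("HC", "SSNHL"), c(n1, n2))),
      age = age,
      gender = sample(c("male", "female"), n1 + n2, replace = TRUE),
      education = rnorm(n1 + n2, 13, 3))
    y <- 0.1 * age + rnorm(n1 + n2)  # depends on age only, not group
    reject[r] <- glm_group_test(cohort, y)$p < 0.05
  }
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.09)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.0005, 90), 0.045)
  expect_equal(bonferroni(0.5, 90), 1)
  p <- runif(10)
  expect_true(all(bonferroni(p, 90) >= p))
  expect_error(bonferroni(1.2, 90), "0, 1")
  expect_error(bonferroni(rep(0.5, 10), 5), "n_tests")
})

test_that("partial correlation residualizes covariates correctly", {
  set.seed(8)
  x <- rnorm(100)
  expect_equal(partial_pearson(x, x)$r, 1)

  # y equal to the covariate exactly: residual correlation ~ 0
  z <- rnorm(100)
  x2 <- rnorm(100)
  res <- partial_pearson(x2, z, covariates = cbind(z = z + 0))
  expect_true(is.na(res$r) || abs(res$r) < 0.2)

  # planted partial correlation recovered at n = 145
  rs <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 145
    covs <- cbind(a = rnorm(n), b = rnorm(n))
    common <- rnorm(n)
    x <- 0.5 * covs[, 1] + sqrt(0.5) * common + sqrt(0.5) * rnorm(n)
    y <- -0.3 * covs[, 2] + sqrt(0.5) * common + sqrt(0.5) * rnorm(n)
    partial_pearson(x, y, covs)$r
  })
  expect_true(all(rs > 0.3 & rs < 0.7))
  expect_equal(mean(rs), 0.5, tolerance = 0.08)

  # p-value degrees of freedom account for the covariates
  res3 <- partial_pearson(rnorm(50), rnorm(50), matrix(rnorm(150), 50))
  expect_equal(res3$df, 50 - 2 - 3)
})

test_that("full group report has the documented structure and sign convention", {
  coh <- generate_cohort(cohort_config(n_controls = 12, n_patients = 12,
                                       seed = 5))
  an <- analyze_cohort(coh$counts, coh$cohort, fn_thresholds = 3,
                       primary_fn = 3, m = 0, seed = 1)
  st <- an$stats
  expect_setequal(st$demographics$variable,
                  c("age", "education", "pta", "gender"))
  expect_true(all(c("cp", "lp", "loce", "ge") %in% st$global$metric))
  expect_equal(nrow(st$nodal), 3 * 90)
  expect_true(all(st$nodal$p_bonferroni >= st$nodal$p))
  # PTA is hugely different between groups; patients have higher PTA so the
  # HC-minus-SSNHL t must be strongly negative
  expect_lt(st$demographics$t[st$demographics$variable == "pta"], -5)
  expect_lt(st$demographics$p[st$demographics$variable == "pta"], 1e-6)
  # planted effect: control Cp exceeds patient Cp -> positive t
  expect_gt(st$global$t[st$global$metric == "cp"], 0)
  # correlations exist for patients' clinical variables
  expect_true(all(c("pta", "thi", "duration") %in% st$correlations$clinical))
})
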