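test_that("information criteria reproduce the published selection arithmetic", {
  # 3-class model: k = 3*8 + 2 = 26 free parameters, n = 200 respondents
  ic3 <- information_criteria(-2664.97, 26, 200)
  expect_equal(unname(ic3["AIC"]), 5381.94)
  expect_equal(unname(ic3["CAIC"]), 5493.70, tolerance = 1e-5)
  expect_equal(unname(round(ic3["BIC"], 1)), 5467.7)
  ic2 <- information_criteria(-2801.49, 17, 200)
  expect_equal(unname(round(ic2["BIC"], 2)), 5693.05)
  # degenerate case
  expect_equal(unname(information_criteria(0, 0, 1)), c(0, 0, 0))
  # n = cards (1800) would NOT reproduce the published numbers
  expect_gt(abs(information_criteria(-2664.97, 26, 1800)["BIC"] - 5467.7), 10)
})

test_that("delta columns recomputed from the criteria match the published table", {
  sweep_ll <- milk_study_class_sweep()
  k <- sweep_ll$classes * 8 + (sweep_ll$classes - 1)
  ic <- t(mapply(information_criteria, sweep_ll$loglik, k, 200))
  tab <- bwsmaxdiff:::add_delta_columns(
    data.frame(classes = sweep_ll$classes, loglik = sweep_ll$loglik,
               AIC = ic[, "AIC"], CAIC = ic[, "CAIC"], BIC = ic[, "BIC"]))
  expect_equal(round(tab$delta_AIC[-1], 2),
               c(4.52, 2.56, 0.58, 0.93, 0.54, 0.43, 0.13))
  expect_equal(round(tab$delta_CAIC[-1], 2),
               c(3.79, 1.81, -0.16, 0.18, -0.20, -0.30, -0.59))
  expect_equal(round(tab$delta_BIC[-1], 2),
               c(3.96, 1.98, 0.01, 0.35, -0.03, -0.14, -0.43))
})

test_that("a one-class model reduces exactly to the pooled estimator", {
  panel <- toy_panel(N = 40, seed = 23)
  lc <- em_fit(panel, 1, reference = "O9")
  pooled <- fit_pooled(panel, reference = "O9")
  expect_equal(lc$loglik, pooled$loglik, tolerance = 1e-6)
  expect_equal(unname(lc$class_beta[1, ]), unname(pooled$beta),
               tolerance = 1e-8)
  expect_equal(lc$shares, 1)
  expect_equal(lc$k_params, 8)
  asg <- assign_classes(lc, panel)
  expect_true(all(asg$assignments$class == 1))
})

test_that("EM fits keep shares and posteriors on the simplex, ordered, and reproducible", {
  d <- design94()
  cls <- milk_study_classes()
  panel <- simulate_panel(dgp_spec("latent_class", d, N = 120,
                                   parameters = list(beta = unname(cls$beta),
                                                     shares = cls$shares),
                                   seed = 29))
  lc <- em_fit(panel, 2, n_starts = 3, seed = 5, reference = "O9")
  expect_equal(sum(lc$shares), 1, tolerance = 1e-10)
  expect_true(all(lc$shares > 0))
  expect_true(!is.unsorted(rev(lc$shares)))  # descending-share order
  expect_equal(unname(rowSums(lc$posteriors)), rep(1, 120), tolerance = 1e-10)
  expect_equal(lc$k_params, 2 * 8 + 1)
  # label-switching canonicalisation makes seeded refits identical
  lc2 <- em_fit(panel, 2, n_starts = 3, seed = 5, reference = "O9")
  expect_identical(lc$class_beta, lc2$class_beta)
  expect_identical(lc$shares, lc2$shares)
  expect_identical(lc$loglik, lc2$loglik)
  # more classes can only improve the maximised log-likelihood
  lc1 <- em_fit(panel, 1, reference = "O9")
  expect_gte(lc$loglik, lc1$loglik)
})

test_that("class sweep delta columns are internally consistent", {
  d <- design94()
  cls <- milk_study_classes()
  panel <- simulate_panel(dgp_spec("latent_class", d, N = 80,
                                   parameters = list(beta = unname(cls$beta),
                                                     shares = cls$shares),
                                   seed = 31))
  tab <- class_sweep(panel, 1, 2, n_starts = 2, seed = 3, reference = "O9")
  expect_equal(tab$classes, 1:2)
  for (col in c("AIC", "CAIC", "BIC")) {
    dcol <- paste0("delta_", col)
    expect_true(is.na(tab[[dcol]][1]))
    expect_equal(tab[[dcol]][2],
                 100 * (tab[[col]][1] - tab[[col]][2]) / tab[[col]][1])
  }
  # identical criteria across consecutive rows would give a zero delta
  flat <- bwsmaxdiff:::add_delta_columns(
    data.frame(classes = 2:3, loglik = c(-10, -10), AIC = c(50, 50),
               CAIC = c(60, 60), BIC = c(55, 55)))
  expect_equal(flat$delta_AIC[2], 0)
})

test_that("per-class preference shares form rows of a stochastic matrix", {
  d <- design94()
  cls <- milk_study_classes()
  panel <- simulate_panel(dgp_spec("latent_class", d, N = 100,
                                   parameters = list(beta = unname(cls$beta),
                                                     shares = cls$shares),
                                   seed = 37))
  lc <- em_fit(panel, 3, n_starts = 3, seed = 7, reference = "O9")
  asg <- assign_classes(lc, panel)
  expect_equal(unname(rowSums(asg$shares)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(asg$assignments$posterior >= 1 / 3 - 1e-12))
  expect_setequal(asg$assignments$respondent_id, panel$respondents)
})

test_that("covariate profiling recovers class-dependent composition", {
  fx <- study_fixture()
  truth <- attr(fx$panel, "truth")
  asg_true <- data.frame(respondent_id = fx$panel$respondents,
                         class = truth$class)
  prof <- profile_classes(asg_true, fx$covariates)
  expect_named(prof, c("income", "head_gender", "head_age", "head_education"))
  rates <- milk_study_covariate_rates()
  for (vn in names(prof)) {
    pct <- as.matrix(prof[[vn]][, -1])
    expect_equal(unname(colSums(pct)), rep(100, 3), tolerance = 1e-9)
    # binomial sampling error around the generating rates: 4 sigma with
    # class sizes >= ~20 at N = 200
    n_c <- table(truth$class)
    gen <- rates[[vn]][prof[[vn]]$level, ]
    se <- sqrt(gen * (100 - gen) / matrix(n_c, nrow(gen), 3, byrow = TRUE))
    expect_true(all(abs(pct - gen) <= 4 * se + 1e-9))
  }
  # single-class edge: the lone column reproduces the marginal distribution
  one <- data.frame(respondent_id = fx$panel$respondents, class = 1L)
  p1 <- profile_classes(one, fx$covariates)$income
  marg <- table(fx$covariates$income)
  expect_equal(p1$class1[match(names(marg), p1$level)],
               unname(100 * as.numeric(marg) / sum(marg)))
})
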