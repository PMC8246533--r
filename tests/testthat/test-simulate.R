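test_that("dgp specifications are dimension-checked", {
  d <- design94()
  expect_error(dgp_spec("pooled", d, 10, list(beta = rep(0, 5))), "dimensions")
  expect_error(dgp_spec("latent_class", d, 10,
                        list(beta = matrix(0, 2, 9), shares = c(0.7, 0.2))),
               "dimensions")
  expect_s3_class(dgp_spec("mixed", d, 10,
                           list(mu = rep(0, 9), sigma = rep(1, 9))),
                  "dgp_spec")
})

test_that("flat utilities produce uniform pair frequencies", {
  d <- design94()
  panel <- simulate_panel(dgp_spec("pooled", d, N = 5000,
                                   parameters = list(beta = rep(0, 9)),
                                   seed = 101))
  # per block, the 12 ordered pairs should be hit N/12 times within 4 sigma
  p0 <- 1 / 12
  bound <- 4 * sqrt(5000 * p0 * (1 - p0))
  for (g in c(1, 5, 9)) {
    sub <- panel$cards[panel$cards$block == g, ]
    counts <- table(factor(paste(sub$best, sub$worst),
                           levels = paste(expand_pairs(d$blocks[[g]])[, 1],
                                          expand_pairs(d$blocks[[g]])[, 2])))
    expect_true(all(abs(counts - 5000 * p0) <= bound))
  }
})

test_that("a dominant option is picked best on almost all of its cards", {
  d <- design94()
  beta <- rep(0, 9); beta[3] <- 10
  panel <- simulate_panel(dgp_spec("pooled", d, N = 300,
                                   parameters = list(beta = beta), seed = 5))
  on_cards <- panel$cards[panel$cards$block %in%
                            which(vapply(d$blocks, function(b) 3 %in% b,
                                         logical(1))), ]
  expect_gt(mean(on_cards$best == 3), 0.99)
})

test_that("simulated pair frequencies match the model probabilities (chi-square)", {
  d <- design94()
  beta <- c(1.2, 0.4, -0.3, 0.8, 0, -0.6, 0.2, 1.5, 0)
  panel <- simulate_panel(dgp_spec("pooled", d, N = 20000,
                                   parameters = list(beta = beta), seed = 71))
  for (g in seq_len(d$b)) {
    pp <- pair_probabilities(beta, d$blocks[[g]])
    sub <- panel$cards[panel$cards$block == g, ]
    obs <- table(factor(paste(sub$best, sub$worst),
                        levels = paste(pp$best, pp$worst)))
    gof <- stats::chisq.test(as.numeric(obs), p = pp$prob)
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("panels are seed-deterministic and extension-stable per respondent", {
  d <- design94()
  spec10 <- dgp_spec("pooled", d, N = 10,
                     parameters = list(beta = c(rep(0.5, 4), rep(0, 5))),
                     seed = 55)
  p1 <- simulate_panel(spec10)
  p2 <- simulate_panel(spec10)
  expect_identical(p1$cards, p2$cards)
  # adding respondents never perturbs earlier respondents' data
  spec15 <- dgp_spec("pooled", d, N = 15,
                     parameters = list(beta = c(rep(0.5, 4), rep(0, 5))),
                     seed = 55)
  p3 <- simulate_panel(spec15)
  expect_identical(p3$cards[p3$cards$respondent <= 10, ], p1$cards)
})

test_that("mixed and latent-class DGPs seal usable truth records", {
  d <- design94()
  mx <- milk_study_mixed()
  pm <- simulate_panel(dgp_spec("mixed", d, N = 20,
                                parameters = list(mu = unname(mx$mu),
                                                  sigma = unname(mx$sigma)),
                                seed = 3))
  tr <- attr(pm, "truth")
  expect_equal(dim(tr$beta), c(20, 9))
  expect_true(all(tr$beta[, 9] == 0))
  expect_false(any(duplicated(tr$beta[, 4])))  # continuous draws differ
  cls <- milk_study_classes()
  pl <- simulate_panel(dgp_spec("latent_class", d, N = 50,
                                parameters = list(beta = unname(cls$beta),
                                                  shares = cls$shares),
                                seed = 3))
  trl <- attr(pl, "truth")
  expect_true(all(trl$class %in% 1:3))
  expect_equal(trl$beta, unname(cls$beta)[trl$class, ])
})

test_that("the packaged study fixture is complete and regenerates byte-identically", {
  fx <- study_fixture()
  expect_equal(length(fx$panel$respondents), 200)
  expect_equal(nrow(fx$panel$cards), 1800)  # 1800 best and 1800 worst picks
  counts <- count_best_worst(fx$panel)
  expect_equal(sum(counts$best), 1800)
  expect_equal(sum(counts$worst), 1800)
  # top-two relative importance matches the generating preference structure
  tab <- score_table(fx$panel)
  expect_setequal(tab$option[tab$rank <= 2], c("O2", "O4"))
  # shipped files reproduce exactly
  shipped <- system.file("extdata", package = "bwsmaxdiff")
  tmp <- file.path(tempdir(), "fixture-regen")
  dir.create(tmp, showWarnings = FALSE)
  write_study_fixture(tmp)
  for (f in c("synthetic_design.json", "synthetic_panel.csv",
              "synthetic_covariates.csv")) {
    expect_identical(readLines(file.path(tmp, f)),
                     readLines(file.path(shipped, f)),
                     label = f)
  }
})
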