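test_that("degenerate mixing reproduces the pooled likelihood exactly", {
  panel <- toy_panel(N = 12, seed = 2)
  mu <- c(0.4, -0.3, 1.2, 0.1, -0.6, 0.8, 0, 0.5, 0)
  Z <- halton_normal_draws(12, 25, 8, seed = 9)
  expect_identical(simulated_loglik(mu, rep(0, 9), panel, Z, reference = "O9"),
                   loglik_pooled(mu, panel))
  # R = 1 with all-zero draws is the pooled likelihood at mu as well
  Z0 <- matrix(0, 12, 8)
  expect_equal(simulated_loglik(mu, c(rep(1, 8), 0), panel, Z0, reference = "O9"),
               loglik_pooled(mu, panel))
})

test_that("the simulated likelihood matches a hand-expanded sum of products", {
  d <- bwsmaxdiff:::new_bws_design(c("a", "b", "c", "d"),
                                   list(c(1, 2, 3), c(2, 3, 4)))
  cards <- data.frame(respondent = rep(1:3, each = 2),
                      block = rep(1:2, 3),
                      best = NA_integer_, worst = NA_integer_)
  for (i in seq_len(nrow(cards))) {
    shown <- d$blocks[[cards$block[i]]]
    cards$best[i] <- shown[1 + i %% 2]
    cards$worst[i] <- shown[2 - i %% 2]
  }
  panel <- bws_panel(d, cards)
  mu <- c(0.5, -0.2, 0.9, 0)
  sigma <- c(0.8, 1.1, 0.3, 0)
  Z <- matrix(c(0.3, -1.2, 0.7, 0.1, -0.4, 1.5,
                -0.9, 0.6, 0.2, -1.1, 0.8, 0.05,
                0.45, -0.7, 1.3, -0.15, 0.9, -2.1), ncol = 3)  # (3*2) x 3
  ## independent expansion: loop over respondents, draws, cards
  ll_oracle <- 0
  for (n in 1:3) {
    pr_sum <- 0
    for (r in 1:2) {
      beta <- mu
      beta[1:3] <- mu[1:3] + sigma[1:3] * Z[(n - 1) * 2 + r, ]
      prod_cards <- 1
      for (i in which(cards$respondent == n)) {
        oracle <- enumerate_pair_probs(beta, d$blocks[[cards$block[i]]])
        hit <- oracle$pairs[, 1] == cards$best[i] &
          oracle$pairs[, 2] == cards$worst[i]
        prod_cards <- prod_cards * oracle$prob[hit]
      }
      pr_sum <- pr_sum + prod_cards
    }
    ll_oracle <- ll_oracle + log(pr_sum / 2)
  }
  expect_equal(simulated_loglik(mu, sigma, panel, Z, reference = 4),
               ll_oracle, tolerance = 1e-10)
})

test_that("the simulated likelihood is invariant to permuting a respondent's draws", {
  panel <- toy_panel(N = 6, seed = 3)
  set.seed(41)
  mu <- rnorm(9); mu[9] <- 0
  sg <- c(abs(rnorm(8)), 0)
  Z <- halton_normal_draws(6, 10, 8, seed = 1)
  Zp <- Z
  perm <- sample(10)
  Zp[10 + seq_len(10), ] <- Z[10 + perm, ]  # shuffle respondent 2's block
  expect_equal(simulated_loglik(mu, sg, panel, Z, reference = "O9"),
               simulated_loglik(mu, sg, panel, Zp, reference = "O9"),
               tolerance = 1e-10)
})

test_that("the analytic simulated-likelihood gradient matches finite differences", {
  panel <- toy_panel(N = 8, seed = 6)
  Z <- halton_normal_draws(8, 15, 8, seed = 2)
  set.seed(43)
  mu <- c(rnorm(8, sd = 0.5), 0)
  sg <- c(rnorm(8, sd = 0.5), 0)
  core <- bwsmaxdiff:::msl_core(mu, sg, panel, Z, gradient = TRUE, ref = 9)
  ll <- function(m, s) bwsmaxdiff:::msl_core(m, s, panel, Z, FALSE, 9)$loglik
  for (t in c(1, 4, 8)) {
    e <- replace(rep(0, 9), t, 1e-6)
    expect_equal(core$grad[t], (ll(mu + e, sg) - ll(mu - e, sg)) / 2e-6,
                 tolerance = 1e-5)
    expect_equal(core$grad[8 + t], (ll(mu, sg + e) - ll(mu, sg - e)) / 2e-6,
                 tolerance = 1e-5)
  }
})

test_that("fitting data simulated without heterogeneity finds no material sigma", {
  # at a true sigma of 0 the likelihood is flat to second order in sigma,
  # so sigma_hat is O(N^-1/4) and boundary Wald z-values are unusable; the
  # null check therefore bounds the magnitude at twice the N^-1/4 scale
  d <- design94()
  beta <- c(1.5, 1, 0.5, 0, -0.5, 0.3, 0.8, -0.2, 0)
  panel <- simulate_panel(dgp_spec("pooled", d, N = 150,
                                   parameters = list(beta = beta), seed = 14))
  fit <- fit_mixed(panel, reference = "O9", R = 50, seed = 7)
  expect_true(all(fit$sigma_abs <= 2 * 150^(-1 / 4)))
  expect_equal(unname(fit$mu[-9]), beta[-9], tolerance = 0.35)
})

test_that("mixed fits are deterministic given (R, seed)", {
  panel <- toy_panel(N = 30, seed = 19)
  f1 <- fit_mixed(panel, reference = "O9", R = 25, seed = 11, maxit = 60)
  f2 <- fit_mixed(panel, reference = "O9", R = 25, seed = 11, maxit = 60)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("population shares reduce to the plug-in softmax when sigma is zero", {
  mu <- c(2, 1, 0.5, 0, -1, 0.3, 0.7, 1.2, 0)
  names(mu) <- paste0("O", 1:9)
  ps <- population_shares(list(mu = mu, sigma = rep(0, 9)), n_draws = 200,
                          seed = 3)
  expect_equal(ps$mean_share, unname(shares_of_preference(mu)),
               tolerance = 1e-12)
  expect_equal(ps$sd_share, rep(0, 9), tolerance = 1e-12)
})

test_that("population mean shares sum to one and follow the study ordering", {
  mx <- milk_study_mixed()
  ps <- population_shares(mx, n_draws = 50000, seed = 5)
  expect_equal(sum(ps$mean_share), 1, tolerance = 1e-12)
  ord <- ps$option[order(-ps$mean_share)]
  expect_identical(ord, c("O4", "O2", "O5", "O7", "O8", "O1", "O3", "O6", "O9"))
})
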