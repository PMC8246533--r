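#' Synthetic best-worst respondents
#'
#' Simulates panels from the three data-generating processes the
#' estimators assume: common utilities (`pooled`), normal random
#' coefficients (`mixed`), or a finite mixture of utility classes
#' (`latent_class`). Each respondent first draws their latent state (class
#' membership or coefficient vector), then answers every card by sampling
#' one ordered (best, worst) pair from the maxdiff pair probabilities.
#' A single base seed is split hierarchically per respondent, so enlarging
#' the panel never perturbs earlier respondents' data.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Specify a data-generating process
#'
#' @param kind One of `"pooled"`, `"mixed"`, `"latent_class"`.
#' @param design A `bws_design`.
#' @param N Number of respondents.
#' @param parameters For `pooled`: list(`beta`); for `mixed`:
#'   list(`mu`, `sigma`); for `latent_class`: list(`beta` = C x v matrix,
#'   `shares`). All utility vectors are full length v.
#' @param covariate_rates Optional named list of per-class column-percentage
#'   matrices (as [milk_study_covariate_rates()]); latent-class DGPs only.
#' @param seed Base seed.
#' @return A `dgp_spec` list.
#' @export
dgp_spec <- function(kind = c("pooled", "mixed", "latent_class"),
                     design, N, parameters, covariate_rates = NULL,
                     seed = 1L) {
  kind <- match.arg(kind)
  v <- design$v
  ok <- switch(kind,
    pooled = length(parameters$beta) == v,
    mixed = length(parameters$mu) == v && length(parameters$sigma) == v,
    latent_class = is.matrix(parameters$beta) && ncol(parameters$beta) == v &&
      length(parameters$shares) == nrow(parameters$beta) &&
      abs(sum(parameters$shares) - 1) < 1e-8 && all(parameters$shares > 0)
  )
  if (!ok) stop("parameter dimensions do not match the design / kind")
  structure(list(kind = kind, design = design, N = as.integer(N),
                 parameters = parameters, covariate_rates = covariate_rates,
                 seed = as.integer(seed)),
            class = "dgp_spec")
}

respondent_seed <- function(base, n) {
  (as.double(base) * 48271 + n * 69621) %% 2147483647
}

#' Simulate a best-worst response panel
#'
#' @param spec A `dgp_spec`.
#' @return A `bws_panel` whose `truth` attribute records the sealed
#'   latent state per respondent (class labels or drawn coefficient
#'   vectors) for parameter-recovery testing.
#' @examples
#' d <- generate_design(9, 9, 4, seed = 1)
#' spec <- dgp_spec("pooled", d, N = 50,
#'                  parameters = list(beta = c(1, 0.5, rep(0, 7))))
#' panel <- simulate_panel(spec)
#' @export
simulate_panel <- function(spec) {
  d <- spec$design
  v <- d$v
  pairs_list <- design_pairs(d)
  rows <- vector("list", spec$N)
  truth_class <- integer(spec$N)
  truth_beta <- matrix(NA_real_, spec$N, v)
  covs <- NULL
  ids <- sprintf("R%03d", seq_len(spec$N))

  for (n in seq_len(spec$N)) {
    set.seed(respondent_seed(spec$seed, n))
    beta <- switch(spec$kind,
      pooled = spec$parameters$beta,
      mixed = spec$parameters$mu +
        abs(spec$parameters$sigma) * stats::rnorm(v) *
          (spec$parameters$sigma != 0),
      latent_class = {
        c_n <- sample.int(length(spec$parameters$shares), 1,
                          prob = spec$parameters$shares)
        truth_class[n] <- c_n
        spec$parameters$beta[c_n, ]
      })
    truth_beta[n, ] <- beta
    best <- integer(d$b); worst <- integer(d$b)
    for (g in seq_len(d$b)) {
      pr <- pairs_list[[g]]
      dd <- beta[pr[, "best"]] - beta[pr[, "worst"]]
      p <- exp(dd - logsumexp(dd))
      pick <- sample.int(nrow(pr), 1, prob = p)
      best[g] <- pr[pick, "best"]
      worst[g] <- pr[pick, "worst"]
    }
    rows[[n]] <- data.frame(respondent = ids[n], block = seq_len(d$b),
                            best = best, worst = worst)
    if (spec$kind == "latent_class" && !is.null(spec$covariate_rates)) {
      draw <- vapply(spec$covariate_rates, function(m) {
        lv <- rownames(m)
        lv[sample.int(length(lv), 1, prob = m[, truth_class[n]])]
      }, character(1))
      covs <- rbind(covs, data.frame(respondent_id = ids[n], t(draw)))
    }
  }
  panel <- bws_panel(d, do.call(rbind, rows), respondents = ids,
                     covariates = covs)
  attr(panel, "truth") <- list(kind = spec$kind, class = truth_class,
                               beta = truth_beta, seed = spec$seed)
  panel
}

#' The packaged study-scale fixture
#'
#' A seed-fixed synthetic stand-in for the (undeposited) milk-allocation
#' survey: 200 respondents on a (9, 9, 4) near-BIBD, generated from the
#' three-class latent structure of [milk_study_classes()] (shares
#' 65/21/14%) with class-dependent categorical covariates following
#' [milk_study_covariate_rates()]. The same deterministic panel ships in
#' `inst/extdata/` (`synthetic_design.json`, `synthetic_panel.csv`,
#' `synthetic_covariates.csv`); re-running this function reproduces those
#' files byte-identically.
#'
#' @return List with `design`, `panel` (a `bws_panel` with covariates and
#'   truth attribute), and `covariates`.
#' @export
study_fixture <- function() {
  design <- generate_design(9, 9, 4, seed = 20170401)
  cls <- milk_study_classes()
  spec <- dgp_spec("latent_class", design, N = 200,
                   parameters = list(beta = cls$beta, shares = cls$shares),
                   covariate_rates = milk_study_covariate_rates(),
                   seed = 20170402)
  panel <- simulate_panel(spec)
  list(design = design, panel = panel, covariates = panel$covariates)
}

#' Write the study fixture files
#'
#' @param dir Output directory.
#' @return Paths of the three files, invisibly.
#' @keywords internal
#' @export
write_study_fixture <- function(dir) {
  fx <- study_fixture()
  dp <- file.path(dir, "synthetic_design.json")
  pp <- file.path(dir, "synthetic_panel.csv")
  cp <- file.path(dir, "synthetic_covariates.csv")
  write_design(fx$design, dp)
  write_panel(fx$panel, pp, covariates_path = cp)
  invisible(c(dp, pp, cp))
}
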