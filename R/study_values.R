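#' Published summaries from the Nairobi milk-allocation study
#'
#' The motivating application is a best-worst scaling survey of 200
#' low-income households in Dagoretti (peri-urban Nairobi, Kenya), each
#' answering nine choice cards of four intrahousehold milk-allocation
#' options under a hypothetical 40% raw-milk price increase. The raw
#' responses were never deposited, but the study's published summary
#' statistics — aggregate best/worst counts, mixed-logit estimates,
#' latent-class estimates and the class-selection criteria — are bundled
#' here. They serve two roles: as worked-example inputs for the counting
#' and share-of-preference transforms, and as data-generating parameters
#' for the synthetic respondent generator.
#'
#' @name milk_study
#' @keywords internal
NULL

#' The nine milk-allocation options
#'
#' @return Data frame `option`, `description`; `O9` ("stop buying raw
#'   milk") is the conventional reference level in all model fits.
#' @export
milk_allocation_options <- function() {
  data.frame(
    option = paste0("O", 1:9),
    description = c(
      "Decrease raw milk for all members, no replacement",
      "Decrease raw milk for all, replace only for children under 4",
      "Decrease raw milk for all, replace for all except children under 4",
      "Decrease raw milk for all, replace for all members",
      "Keep quantities for children under 4, decrease for the rest",
      "Decrease for children under 4 without replacement, keep for adults",
      "Decrease for children under 4 with replacement, keep for adults",
      "Keep the same quantities by increasing the milk budget",
      "Stop buying raw milk"
    )
  )
}

#' Aggregate best/worst counts from the milk study
#'
#' Per-option totals over 200 respondents x 9 cards. The published worst
#' column sums to 1798 rather than 1800 (a printing slip in one cell); the
#' counts are reproduced as published.
#'
#' @return Data frame `option`, `best`, `worst`.
#' @export
milk_study_counts <- function() {
  data.frame(
    option = paste0("O", 1:9),
    best = c(45L, 494L, 24L, 518L, 305L, 12L, 239L, 146L, 17L),
    worst = c(205L, 13L, 235L, 17L, 45L, 319L, 48L, 217L, 699L)
  )
}

#' Mixed-logit estimates from the milk study
#'
#' Mean and standard-deviation estimates of the random utility coefficient
#' of each option (reference O9 fixed at 0), from a panel mixed-logit
#' maxdiff fit. The O6 standard deviation was reported with a negative
#' sign; its sign is unidentified (the likelihood depends on |sigma|).
#'
#' @return List with named numeric vectors `mu` and `sigma` (length 9,
#'   O9 = 0) and `reference`.
#' @export
milk_study_mixed <- function() {
  opt <- paste0("O", 1:9)
  mu <- c(2.877, 5.594, 2.607, 5.843, 4.688, 2.315, 4.315, 2.950, 0)
  sigma <- c(0.696, 1.113, 0.472, 1.725, 1.418, -0.566, 1.079, 2.409, 0)
  list(mu = stats::setNames(mu, opt), sigma = stats::setNames(sigma, opt),
       reference = "O9")
}

#' Latent-class estimates from the milk study
#'
#' Three-class maxdiff utilities (reference O9 = 0 in each class) and the
#' class shares 65/21/14%.
#'
#' @return List with `beta` (3 x 9 matrix, rows class1..class3), `shares`
#'   and `reference`.
#' @export
milk_study_classes <- function() {
  opt <- paste0("O", 1:9)
  beta <- rbind(
    class1 = c(4.098, 6.533, 3.876, 7.129, 5.620, 3.699, 5.652, 3.484, 0),
    class2 = c(3.264, 5.363, 3.252, 5.006, 5.154, 2.789, 4.439, 6.031, 0),
    class3 = c(0.354, 1.487, -0.164, 1.151, 0.766, -0.341, 0.564, -1.226, 0)
  )
  colnames(beta) <- opt
  list(beta = beta, shares = c(0.65, 0.21, 0.14), reference = "O9")
}

#' Class-selection log-likelihoods from the milk study
#'
#' Maximised log-likelihoods of the 2- to 9-class latent-class fits, the
#' raw material for the AIC/BIC/CAIC selection table.
#'
#' @return Data frame `classes`, `loglik`.
#' @export
milk_study_class_sweep <- function() {
  data.frame(
    classes = 2:9,
    loglik = c(-2801.49, -2664.97, -2586.98, -2562.83,
               -2529.5, -2506.58, -2486.44, -2474.2)
  )
}

#' Class-conditional covariate rates from the milk study
#'
#' Categorical household-profile distributions per latent class (column
#' percentages), used by the synthetic generator to emulate
#' class-dependent covariates: income tier, household-head gender, age
#' band and education level.
#'
#' @return Named list of 3-column matrices (one column per class, rows
#'   are category levels, columns sum to 100).
#' @export
milk_study_covariate_rates <- function() {
  cls <- paste0("class", 1:3)
  mk <- function(m, levels) {
    m <- matrix(m, ncol = 3, dimnames = list(levels, cls))
    sweep(m, 2, colSums(m), "/") * 100
  }
  list(
    income = mk(c(16.9, 39.2, 43.9,  19.0, 26.2, 54.8,  28.6, 42.9, 28.5),
                c("below_10000", "10001_20000", "20001_30000")),
    head_gender = mk(c(76.9, 23.1,  85.7, 14.3,  89.3, 10.7),
                     c("male", "female")),
    head_age = mk(c(37.7, 43.8, 13.1, 5.4,  38.1, 40.5, 16.7, 4.7,
                    25.0, 53.6, 10.7, 10.7),
                  c("18_29", "30_39", "40_49", "50_plus")),
    head_education = mk(c(29.5, 44.9, 25.6,  42.5, 47.5, 10.0,
                          28.0, 60.0, 12.0),
                        c("primary_vocational", "secondary",
                          "technical_university"))
  )
}
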