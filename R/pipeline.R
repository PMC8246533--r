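#' End-to-end analysis pipeline
#'
#' Runs the full best-worst analysis on a panel — counting scores, pooled
#' fit, mixed-logit fit with population shares, latent-class sweep, the
#' selected-class estimates with shares of preference, and covariate
#' profiling — and writes one CSV per publication-style table plus a
#' machine-readable settings echo. Two runs with the same configuration
#' produce byte-identical outputs.
#'
#' @param config A list or path to a YAML/JSON file with entries:
#'   `design` (path), `panel` (path), `covariates` (optional path),
#'   `out_dir`, and optional `settings`: `reference` (default "O9" if
#'   present else last item), `draws` (default 500), `draw_seed`,
#'   `classes` (class count for the reported class table, default 3),
#'   `class_range` (default `c(2, 5)`), `starts` (default 20),
#'   `seed` (default 1), `share_draws` (default 10000).
#' @return Invisibly, a list with every fitted object and the written
#'   file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  st <- config$settings
  default <- function(x, d) if (is.null(x)) d else x
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  design <- stage("design", read_design(config$design))
  panel <- stage("panel",
                 read_panel(config$panel, design,
                            covariates_path = config$covariates))
  reference <- default(st$reference,
                       if ("O9" %in% design$items) "O9"
                       else design$items[design$v])
  draws <- default(st$draws, 500L)
  seed <- default(st$seed, 1L)
  draw_seed <- default(st$draw_seed, seed)
  n_classes <- default(st$classes, 3L)
  class_range <- default(st$class_range, c(2L, 5L))
  starts <- default(st$starts, 20L)
  share_draws <- default(st$share_draws, 10000L)

  paths <- character(0)
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
    p
  }

  ## scores table (counting statistics)
  scores <- stage("score", score_table(panel))
  emit(as.data.frame(scores), "scores.csv")

  ## pooled baseline
  pooled <- stage("fit-pooled", fit_pooled(panel, reference = reference))

  ## mixed logit + population shares
  mixed <- stage("fit-mixed",
                 fit_mixed(panel, reference = reference, R = draws,
                           seed = draw_seed))
  pshares <- stage("shares",
                   population_shares(mixed, n_draws = share_draws,
                                     seed = draw_seed))
  emit(data.frame(option = names(mixed$mu),
                  mean = mixed$mu, se_mean = mixed$se_mu,
                  sd = mixed$sigma, sd_abs = mixed$sigma_abs,
                  se_sd = mixed$se_sigma,
                  share_mean = pshares$mean_share,
                  share_sd = pshares$sd_share),
       "mixed_estimates.csv")

  ## latent-class sweep and selected model
  sweep_tab <- stage("sweep",
                     class_sweep(panel, class_range[1], class_range[2],
                                 n_starts = starts, seed = seed,
                                 reference = reference))
  emit(sweep_tab[setdiff(names(sweep_tab), "ok")], "class_sweep.csv")

  lc <- stage("fit-lc",
              em_fit(panel, n_classes, n_starts = starts, seed = seed,
                     reference = reference))
  asg <- assign_classes(lc, panel)
  lc_tab <- data.frame(option = colnames(lc$class_beta))
  for (c in seq_len(lc$C)) {
    lc_tab[[sprintf("class%d_coef", c)]] <- lc$class_beta[c, ]
    lc_tab[[sprintf("class%d_se", c)]] <- lc$class_se[c, ]
    lc_tab[[sprintf("class%d_sp", c)]] <- asg$shares[c, ]
  }
  emit(lc_tab, "class_estimates.csv")

  ## covariate profiling
  profiles <- NULL
  if (!is.null(panel$covariates)) {
    profiles <- stage("profile",
                      profile_classes(asg$assignments, panel$covariates))
    prof_tab <- do.call(rbind, lapply(names(profiles), function(vn) {
      df <- profiles[[vn]]
      cbind(data.frame(covariate = vn), df)
    }))
    emit(prof_tab, "class_profiles.csv")
  }

  echo <- list(
    design = config$design, panel = config$panel,
    covariates = config$covariates,
    settings = list(reference = reference, draws = draws, seed = seed,
                    draw_seed = draw_seed, classes = n_classes,
                    class_range = class_range, starts = starts,
                    share_draws = share_draws),
    loglik = list(pooled = pooled$loglik, mixed = mixed$loglik,
                  latent_class = lc$loglik)
  )
  echo_path <- file.path(out_dir, "settings_echo.json")
  jsonlite::write_json(echo, echo_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, echo_path)

  invisible(list(scores = scores, pooled = pooled, mixed = mixed,
                 population_shares = pshares, sweep = sweep_tab, lc = lc,
                 assignments = asg, profiles = profiles, paths = paths))
}
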