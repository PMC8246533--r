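#' Latent-class maxdiff estimation
#'
#' Finite-mixture maxdiff model: C classes with class-specific utilities
#' beta_c (reference pinned at 0 per class) and mixture shares pi_c.
#' Estimated by EM — E-step posteriors proportional to pi_c times the
#' respondent's panel likelihood under class c; M-step posterior-weighted
#' pooled maxdiff fits per class plus the share update. Class count is
#' chosen by AIC/BIC/CAIC over a sweep, with the percentage-improvement
#' (delta) columns reported rather than an automatic pick.
#'
#' @name latent_class
#' @keywords internal
NULL

## N x C matrix of per-respondent panel log-likelihoods under each class
class_loglik_matrix <- function(class_beta, panel) {
  d <- panel$design
  pairs_list <- design_pairs(d)
  cds <- panel$cards
  C <- nrow(class_beta)
  N <- n_respondents(panel)
  L <- matrix(0, N, C)
  for (c in seq_len(C)) {
    beta <- class_beta[c, ]
    lse <- block_lse(beta, pairs_list)
    contrib <- beta[cds$best] - beta[cds$worst] - lse[cds$block]
    L[, c] <- as.numeric(rowsum(contrib, cds$respondent))
  }
  L
}

#' Fit a latent-class maxdiff model by EM
#'
#' Best of `n_starts` seeded random starts (jittered pooled-fit
#' initialisation); within each start, EM iterates until the
#' log-likelihood improves by less than `tol`. The log-likelihood is
#' checked to be non-decreasing at every iteration. Classes in the
#' returned model are ordered by descending share.
#'
#' @param panel A complete `bws_panel`.
#' @param C Number of classes (C = 1 reduces exactly to [fit_pooled()]).
#' @param n_starts Random starts (default 20).
#' @param seed Seed for the starts.
#' @param reference Reference option (default last item).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-7).
#' @param max_em EM iteration cap per start.
#' @return A `bws_lc` fit: `class_beta` (C x v), `class_se`, `shares`,
#'   `posteriors` (N x C), `loglik`, `k_params`, `criteria`
#'   (AIC/BIC/CAIC at n = respondents), `C`, `reference`.
#' @export
em_fit <- function(panel, C, n_starts = 20L, seed = 1L, reference = NULL,
                   tol = 1e-7, max_em = 500L) {
  stopifnot(C >= 1)
  d <- panel$design
  v <- d$v
  ref <- resolve_reference(reference, d)
  N <- n_respondents(panel)
  pooled <- fit_pooled(panel, reference = ref)

  if (C == 1) {
    model <- list(
      C = 1L, class_beta = matrix(pooled$beta, 1, v,
                                  dimnames = list("class1", d$items)),
      class_se = matrix(pooled$se, 1, v, dimnames = list("class1", d$items)),
      shares = 1, posteriors = matrix(1, N, 1),
      loglik = pooled$loglik, reference = d$items[ref], ref_index = ref,
      n_iter = 0L, converged = TRUE
    )
    return(finish_lc(model, N, v))
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed((as.integer(seed) * 1009L + s) %% .Machine$integer.max)
    class_beta <- matrix(rep(pooled$beta, each = C), C, v,
                         dimnames = list(paste0("class", seq_len(C)), d$items))
    class_beta <- class_beta + matrix(stats::rnorm(C * v), C, v)
    class_beta[, ref] <- 0
    pi_c <- rep(1 / C, C)
    res <- tryCatch(
      em_run(panel, class_beta, pi_c, ref, tol, max_em),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$loglik > best$loglik))
      best <- res
  }
  if (is.null(best))
    stop("all EM starts failed (degenerate classes); try more starts")
  finish_lc(best, N, v)
}

em_run <- function(panel, class_beta, pi_c, ref, tol, max_em) {
  C <- nrow(class_beta)
  ll_old <- -Inf
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_em)) {
    ## E-step
    L <- class_loglik_matrix(class_beta, panel)
    A <- sweep(L, 2, log(pi_c), "+")
    m <- apply(A, 1, max)
    lse <- m + log(rowSums(exp(A - m)))
    ll <- sum(lse)
    if (ll < ll_old - 1e-8)
      stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
    post <- exp(A - lse)
    if (any(colMeans(post) < 1e-6))
      stop("empty class during EM")
    if (ll - ll_old < tol) { ll_old <- ll; converged <- TRUE; break }
    ll_old <- ll
    ## M-step
    pi_c <- colMeans(post)
    for (c in seq_len(C)) {
      w <- post[panel$cards$respondent, c]
      fit <- fit_pooled(panel, reference = ref, weights = w,
                        start = class_beta[c, -ref], grad_tol = 1e-5)
      class_beta[c, ] <- fit$beta
    }
  }
  list(C = C, class_beta = class_beta, shares = pi_c, posteriors = post,
       loglik = ll_old, reference = panel$design$items[ref], ref_index = ref,
       n_iter = it, converged = converged, panel = panel)
}

finish_lc <- function(model, N, v) {
  ## canonical order: descending share (label-switching normalisation)
  ord <- order(model$shares, decreasing = TRUE)
  model$shares <- model$shares[ord]
  model$class_beta <- model$class_beta[ord, , drop = FALSE]
  rownames(model$class_beta) <- paste0("class", seq_len(model$C))
  model$posteriors <- model$posteriors[, ord, drop = FALSE]
  colnames(model$posteriors) <- rownames(model$class_beta)
  if (!is.null(model$class_se)) {
    model$class_se <- model$class_se[ord, , drop = FALSE]
    rownames(model$class_se) <- rownames(model$class_beta)
  } else if (!is.null(model$panel)) {
    ## Wald standard errors from a posterior-weighted fit per class
    se <- matrix(0, model$C, v, dimnames = dimnames(model$class_beta))
    for (c in seq_len(model$C)) {
      w <- model$posteriors[model$panel$cards$respondent, c]
      fit <- fit_pooled(model$panel, reference = model$ref_index, weights = w,
                        start = model$class_beta[c, -model$ref_index])
      se[c, ] <- fit$se
    }
    model$class_se <- se
  }
  model$panel <- NULL
  model$k_params <- model$C * (v - 1) + (model$C - 1)
  model$criteria <- information_criteria(model$loglik, model$k_params, N)
  model$n_respondents <- N
  class(model) <- c("bws_lc", "bws_fit")
  model
}

#' Information criteria for model selection
#'
#' `AIC = -2 LL + 2 k`, `BIC = -2 LL + k ln(n)`,
#' `CAIC = -2 LL + k (ln(n) + 1)`, with `n` the number of respondents
#' (the independent panel units), not the number of cards.
#'
#' @param loglik Maximised log-likelihood.
#' @param k_params Number of free parameters
#'   (`C*(v-1) + (C-1)` for a C-class model).
#' @param n Number of respondents.
#' @return Named vector `AIC`, `BIC`, `CAIC`.
#' @examples
#' information_criteria(-2664.97, 26, 200)   # AIC 5381.94, CAIC 5493.70
#' @export
information_criteria <- function(loglik, k_params, n) {
  stopifnot(n >= 1, k_params >= 0)
  c(AIC = -2 * loglik + 2 * k_params,
    BIC = -2 * loglik + k_params * log(n),
    CAIC = -2 * loglik + k_params * (log(n) + 1))
}

#' Sweep the number of latent classes
#'
#' Fits C = `C_min` .. `C_max` and tabulates log-likelihood, AIC, BIC,
#' CAIC and their percentage improvements
#' `delta_IC(C) = 100 * (IC(C-1) - IC(C)) / IC(C-1)` over the previous
#' row. Rows whose fit fails are kept with `NA` and flagged. The table is
#' reported for inspection — the class count where the deltas level off is
#' not auto-selected.
#'
#' @param panel A complete `bws_panel`.
#' @param C_min,C_max Class-count range (default 2..5).
#' @param n_starts,seed,reference Passed to [em_fit()].
#' @return Data frame `classes`, `loglik`, `AIC`, `delta_AIC`, `CAIC`,
#'   `delta_CAIC`, `BIC`, `delta_BIC`, `ok`; attribute `models` holds the
#'   fitted `bws_lc` objects.
#' @export
class_sweep <- function(panel, C_min = 2L, C_max = 5L, n_starts = 20L,
                        seed = 1L, reference = NULL) {
  stopifnot(C_min >= 1, C_max >= C_min)
  Cs <- seq.int(C_min, C_max)
  models <- vector("list", length(Cs))
  rows <- lapply(seq_along(Cs), function(i) {
    m <- tryCatch(em_fit(panel, Cs[i], n_starts = n_starts,
                         seed = seed + i, reference = reference),
                  error = function(e) NULL)
    models[[i]] <<- m
    if (is.null(m))
      return(data.frame(classes = Cs[i], loglik = NA_real_, AIC = NA_real_,
                        CAIC = NA_real_, BIC = NA_real_, ok = FALSE))
    data.frame(classes = Cs[i], loglik = m$loglik, AIC = m$criteria["AIC"],
               CAIC = m$criteria["CAIC"], BIC = m$criteria["BIC"], ok = TRUE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- add_delta_columns(tab)
  attr(tab, "models") <- models
  tab
}

## percentage improvement over the previous row for each criterion column
add_delta_columns <- function(tab) {
  delta <- function(x) c(NA, 100 * (utils::head(x, -1) - x[-1]) / utils::head(x, -1))
  out <- data.frame(classes = tab$classes, loglik = tab$loglik,
                    AIC = tab$AIC, delta_AIC = delta(tab$AIC),
                    CAIC = tab$CAIC, delta_CAIC = delta(tab$CAIC),
                    BIC = tab$BIC, delta_BIC = delta(tab$BIC))
  if ("ok" %in% names(tab)) out$ok <- tab$ok
  out
}

#' Posterior class assignment and per-class preference shares
#'
#' Modal-posterior (hard) assignment of each respondent plus the
#' share-of-preference transform of each class's utilities.
#'
#' @param model A `bws_lc` fit.
#' @param panel The panel it was fitted to (for respondent identifiers).
#' @return List with `assignments` (data frame `respondent_id`, `class`,
#'   `posterior`) and `shares` (C x v matrix, rows summing to 1).
#' @export
assign_classes <- function(model, panel) {
  cls <- max.col(model$posteriors, ties.method = "first")
  shares <- t(apply(model$class_beta, 1, shares_of_preference))
  colnames(shares) <- colnames(model$class_beta)
  list(
    assignments = data.frame(
      respondent_id = panel$respondents,
      class = cls,
      posterior = model$posteriors[cbind(seq_along(cls), cls)]
    ),
    shares = shares
  )
}

#' Cross-tabulate class membership by covariate levels
#'
#' Column-percentage composition of each class per covariate, the standard
#' post-hoc profiling of latent classes by household characteristics.
#' Respondents missing a covariate are dropped for that covariate only,
#' with the retained count noted.
#'
#' @param assignments Data frame from [assign_classes()] (columns
#'   `respondent_id`, `class`).
#' @param covariates Data frame keyed by `respondent_id`; all other
#'   columns are treated as categorical.
#' @return Named list (one entry per covariate) of data frames
#'   `level`, one `class<c>` percentage column per class (each column
#'   summing to 100), with attribute `n_used`.
#' @export
profile_classes <- function(assignments, covariates) {
  stopifnot("respondent_id" %in% names(covariates))
  merged <- merge(assignments, covariates, by = "respondent_id")
  vars <- setdiff(names(covariates), "respondent_id")
  out <- list()
  for (vn in vars) {
    keep <- !is.na(merged[[vn]]) & merged[[vn]] != ""
    sub <- merged[keep, ]
    tb <- table(sub[[vn]], sub$class)
    pct <- sweep(tb, 2, pmax(colSums(tb), 1), "/") * 100
    df <- data.frame(level = rownames(pct), check.names = FALSE)
    for (c in colnames(pct)) df[[paste0("class", c)]] <- as.numeric(pct[, c])
    attr(df, "n_used") <- sum(keep)
    out[[vn]] <- df
  }
  out
}

#' @export
print.bws_lc <- function(x, ...) {
  cat(sprintf("latent-class maxdiff fit: C = %d, logLik = %.2f, k = %d\n",
              x$C, x$loglik, x$k_params))
  cat(sprintf("  shares: %s\n",
              paste(sprintf("%.3f", x$shares), collapse = " ")))
  cat(sprintf("  AIC %.2f  BIC %.2f  CAIC %.2f (n = %d respondents)\n",
              x$criteria["AIC"], x$criteria["BIC"], x$criteria["CAIC"],
              x$n_respondents))
  print(round(x$class_beta, 3))
  invisible(x)
}
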