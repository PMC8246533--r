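#' The maxdiff choice model
#'
#' Under the maxdiff view of a best-worst task, a respondent facing a card
#' of J options simultaneously chooses the ordered pair (best, worst) that
#' maximises the utility difference. With option utilities beta, the
#' probability of picking pair (i, j) is
#' `exp(beta_i - beta_j) / sum over ordered pairs (k, l) of exp(beta_k - beta_l)`.
#' All probability computations here are log-sum-exp stabilised. One
#' utility (the reference option) is pinned to zero for identification.
#'
#' @name maxdiff
#' @keywords internal
NULL

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(X) {
  m <- apply(X, 1, max)
  m + log(rowSums(exp(X - m)))
}

#' Maxdiff pair probabilities on one card
#'
#' @param beta Named or positional utilities covering all shown items
#'   (length v, indexed by `shown`).
#' @param shown Integer indices of the card's shown items.
#' @return Data frame `best`, `worst`, `prob` over the J(J-1) ordered
#'   pairs, probabilities summing to 1.
#' @examples
#' pair_probabilities(c(2, 1, 0, -1), shown = 1:4)
#' @export
pair_probabilities <- function(beta, shown) {
  pr <- expand_pairs(shown)
  d <- beta[pr[, "best"]] - beta[pr[, "worst"]]
  lse <- logsumexp(d)
  data.frame(best = pr[, "best"], worst = pr[, "worst"],
             prob = exp(d - lse))
}

## per-block ordered-pair index matrices, computed once per design
design_pairs <- function(design) {
  lapply(design$blocks, expand_pairs)
}

## per-block log normalising constants for a full utility vector
block_lse <- function(beta, pairs_list) {
  vapply(pairs_list,
         function(pr) logsumexp(beta[pr[, "best"]] - beta[pr[, "worst"]]),
         numeric(1))
}

#' Pooled maxdiff log-likelihood and gradient
#'
#' Sum over all cards of the log probability of the observed (best, worst)
#' pair under common utilities. Optional per-card weights support the
#' posterior-weighted M-step of the latent-class estimator.
#'
#' @param beta Full utility vector (length v, reference entry 0).
#' @param panel A `bws_panel`.
#' @param weights Optional per-card weights (default 1).
#' @return `loglik_pooled`: the log-likelihood. `loglik_pooled_grad`: its
#'   gradient with respect to the full beta vector.
#' @export
loglik_pooled <- function(beta, panel, weights = NULL) {
  cds <- panel$cards
  if (is.null(weights)) weights <- rep(1, nrow(cds))
  lse <- block_lse(beta, design_pairs(panel$design))
  sum(weights * (beta[cds$best] - beta[cds$worst] - lse[cds$block]))
}

#' @rdname loglik_pooled
#' @export
loglik_pooled_grad <- function(beta, panel, weights = NULL) {
  cds <- panel$cards
  v <- panel$design$v
  if (is.null(weights)) weights <- rep(1, nrow(cds))
  pairs_list <- design_pairs(panel$design)
  ## observed part: weighted net-best counts per option
  g <- vapply(seq_len(v), function(t) {
    sum(weights[cds$best == t]) - sum(weights[cds$worst == t])
  }, numeric(1))
  ## expected part: per block, the model's expected net-best per option,
  ## scaled by the total weight of cards in that block
  wblock <- vapply(seq_along(pairs_list),
                   function(gq) sum(weights[cds$block == gq]), numeric(1))
  for (gq in seq_along(pairs_list)) {
    if (wblock[gq] == 0) next
    pr <- pairs_list[[gq]]
    d <- beta[pr[, "best"]] - beta[pr[, "worst"]]
    p <- exp(d - logsumexp(d))
    s <- numeric(v)
    for (row in seq_len(nrow(pr))) {
      s[pr[row, "best"]] <- s[pr[row, "best"]] + p[row]
      s[pr[row, "worst"]] <- s[pr[row, "worst"]] - p[row]
    }
    g <- g - wblock[gq] * s
  }
  g
}

expand_free <- function(theta, v, ref) {
  beta <- numeric(v)
  beta[-ref] <- theta
  beta
}

#' Fit the pooled (conditional-logit) maxdiff model
#'
#' Maximum likelihood over the v-1 free utilities with the reference
#' option pinned at zero, by BFGS with the analytic gradient. Standard
#' errors come from the inverse observed information (numerically
#' differentiated analytic gradient at the optimum).
#'
#' @param panel A `bws_panel`.
#' @param reference Reference option label or index (default the last item).
#' @param weights Optional per-card weights (latent-class M-step use).
#' @param start Optional starting values for the free utilities.
#' @param grad_tol Convergence check: warn if the gradient sup-norm at the
#'   reported optimum exceeds this (default 1e-6).
#' @return A `bws_fit` list: `beta` (full, reference = 0), `se`,
#'   `covariance` (free parameters), `loglik`, `n_obs`, `reference`,
#'   `convergence` diagnostics.
#' @export
fit_pooled <- function(panel, reference = NULL, weights = NULL, start = NULL,
                       grad_tol = 1e-6) {
  d <- panel$design
  v <- d$v
  ref <- resolve_reference(reference, d)
  cds <- panel$cards
  seen <- unique(c(cds$best, cds$worst))
  missing <- setdiff(setdiff(seq_len(v), ref), seen)
  if (length(missing))
    warning("option(s) never picked best or worst: ",
            paste(d$items[missing], collapse = ", "),
            "; estimates may be poorly identified")
  if (is.null(start)) start <- numeric(v - 1)
  negll <- function(th) -loglik_pooled(expand_free(th, v, ref), panel, weights)
  neggr <- function(th) -loglik_pooled_grad(expand_free(th, v, ref), panel,
                                            weights)[-ref]
  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  ## Newton polish: the pooled likelihood is concave, so a few damped
  ## Newton steps drive the gradient sup-norm below grad_tol
  gfinal <- -neggr(opt$par)
  H <- stats::optimHess(opt$par, negll, neggr)
  polish <- 0L
  while (max(abs(gfinal)) > grad_tol && polish < 10L) {
    step <- tryCatch(solve(H, gfinal), error = function(e) NULL)
    if (is.null(step)) break
    cand <- opt$par + step
    if (negll(cand) > opt$value + 1e-8) break
    opt$par <- cand
    opt$value <- negll(cand)
    gfinal <- -neggr(opt$par)
    H <- stats::optimHess(opt$par, negll, neggr)
    polish <- polish + 1L
  }
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, v - 1, v - 1))
  se_free <- sqrt(pmax(diag(cov), 0))
  if (any(!is.finite(se_free)))
    warning("non-finite standard errors: possible separation ",
            "(an option always best or always worst)")
  beta <- expand_free(opt$par, v, ref)
  names(beta) <- d$items
  se <- rep(0, v); se[-ref] <- se_free; names(se) <- d$items
  structure(list(
    beta = beta, se = se, covariance = cov,
    loglik = -opt$value, n_obs = nrow(cds),
    reference = d$items[ref], ref_index = ref,
    convergence = list(code = opt$convergence,
                       grad_norm = max(abs(gfinal)))
  ), class = c("bws_pooled", "bws_fit"))
}

resolve_reference <- function(reference, design) {
  if (is.null(reference)) return(design$v)
  if (is.character(reference)) {
    ref <- match(reference, design$items)
    if (is.na(ref)) stop("unknown reference option: ", reference)
    return(ref)
  }
  as.integer(reference)
}

#' Shares of preference
#'
#' The softmax transform of option utilities: the forecast probability that
#' each option is picked as best among all v options,
#' `S_i = exp(beta_i) / sum_m exp(beta_m)`. Shares sum to one and are
#' ratio-scaled: `S_i / S_j = exp(beta_i - beta_j)`, so an option with
#' twice the share is "twice as important".
#'
#' @param beta Utility vector over all options (reference = 0), or a
#'   `bws_fit` object.
#' @return Named numeric vector of shares summing to 1.
#' @examples
#' cls <- milk_study_classes()
#' round(shares_of_preference(cls$beta["class2", ]), 3)   # O8 = 0.376
#' @export
shares_of_preference <- function(beta) {
  if (inherits(beta, "bws_fit")) beta <- beta$beta
  s <- exp(beta - max(beta))
  s / sum(s)
}

#' @export
print.bws_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik = %.2f on %d cards (reference %s)\n",
              class(x)[1], x$loglik, x$n_obs, x$reference))
  tab <- data.frame(option = names(x$beta), estimate = round(x$beta, 3),
                    se = round(x$se, 3),
                    share = round(shares_of_preference(x$beta), 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
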