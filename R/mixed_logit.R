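#' Mixed-logit maxdiff estimation
#'
#' Random-coefficient extension of the maxdiff model: respondent n's
#' utilities are beta_n = mu + sigma * z_n with independent standard-normal
#' z_n per option (diagonal mixing; the reference option has mu = sigma = 0).
#' The panel structure enters through the per-respondent product of card
#' probabilities inside the simulated likelihood
#' `sum_n log( (1/R) sum_r prod_cards P(best, worst | mu + sigma z_nr) )`,
#' averaged over R quasi-random (Halton) draws per respondent. `sigma` is
#' unconstrained in estimation — the likelihood is even in each sigma
#' because the normal draws are symmetric — so its sign is not identified
#' and magnitudes `|sigma|` are what matter.
#'
#' @name mixed_logit
#' @keywords internal
NULL

## radical-inverse (generalized Halton) sequence in base p with a digit
## permutation fixing 0, evaluated at integer indices
radical_inverse <- function(idx, p, perm) {
  u <- numeric(length(idx))
  f <- 1 / p
  x <- idx
  while (any(x > 0)) {
    d <- x %% p
    u <- u + perm[d + 1] * f
    f <- f / p
    x <- x %/% p
  }
  u
}

#' Scrambled-Halton standard-normal draws
#'
#' One low-discrepancy sequence per dimension (consecutive primes), with a
#' seeded random digit permutation per dimension (0 held fixed), the first
#' `burn` points dropped, and the inverse-normal transform applied. Rows
#' are respondent-major: respondent n owns rows `(n-1)*R + 1 .. n*R`.
#'
#' @param N Respondents.
#' @param R Draws per respondent.
#' @param dims Number of random coefficients.
#' @param seed Integer seed (drives the digit permutations only).
#' @param burn Initial points to discard (default 50).
#' @return An `(N*R) x dims` matrix of standard-normal variates.
#' @export
halton_normal_draws <- function(N, R, dims, seed = 1L, burn = 50L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53)
  if (dims > length(primes)) stop("too many dimensions for the prime table")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  idx <- burn + seq_len(N * R)
  Z <- matrix(0, N * R, dims)
  for (d in seq_len(dims)) {
    p <- primes[d]
    perm <- c(0, sample(seq_len(p - 1)))
    u <- radical_inverse(idx, p, perm)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    Z[, d] <- stats::qnorm(u)
  }
  Z
}

## complete-panel choice matrices: N x b of best / worst item indices
panel_choice_matrices <- function(panel) {
  N <- n_respondents(panel)
  b <- panel$design$b
  cds <- panel$cards
  if (nrow(cds) != N * b)
    stop("mixed-logit and latent-class estimation require a complete panel")
  Best <- matrix(NA_integer_, N, b)
  Worst <- matrix(NA_integer_, N, b)
  Best[cbind(cds$respondent, cds$block)] <- cds$best
  Worst[cbind(cds$respondent, cds$block)] <- cds$worst
  list(best = Best, worst = Worst)
}

## core simulated log-likelihood; returns LL and, if gradient = TRUE, the
## gradient with respect to (mu, sigma) over the free (non-reference) options
msl_core <- function(mu, sigma, panel, Z, gradient = FALSE, ref) {
  d <- panel$design
  v <- d$v
  N <- n_respondents(panel)
  NR <- nrow(Z)
  R <- NR / N
  ch <- panel_choice_matrices(panel)
  pairs_list <- design_pairs(d)

  Zfull <- matrix(0, NR, v)
  Zfull[, setdiff(seq_len(v), ref)] <- Z
  B <- matrix(mu, NR, v, byrow = TRUE) + matrix(sigma, NR, v, byrow = TRUE) * Zfull

  S <- numeric(NR)                    # per-(n, r) panel log-probability
  A <- if (gradient) matrix(0, NR, v) # expected net-best per option
  nrep <- rep(seq_len(N), each = R)
  for (g in seq_len(d$b)) {
    pr <- pairs_list[[g]]
    D <- B[, pr[, "best"], drop = FALSE] - B[, pr[, "worst"], drop = FALSE]
    m <- D[cbind(seq_len(NR), max.col(D, ties.method = "first"))]
    lse <- m + log(rowSums(exp(D - m)))
    bcol <- ch$best[cbind(nrep, g)]
    wcol <- ch$worst[cbind(nrep, g)]
    S <- S + B[cbind(seq_len(NR), bcol)] - B[cbind(seq_len(NR), wcol)] - lse
    if (gradient) {
      P <- exp(D - lse)
      for (col in seq_len(nrow(pr))) {
        A[, pr[col, "best"]] <- A[, pr[col, "best"]] + P[, col]
        A[, pr[col, "worst"]] <- A[, pr[col, "worst"]] - P[, col]
      }
    }
  }
  Smat <- matrix(S, nrow = R)         # columns = respondents
  mcol <- apply(Smat, 2, max)
  lse_n <- mcol + log(colSums(exp(sweep(Smat, 2, mcol))))
  ll <- sum(lse_n - log(R))
  if (!gradient) return(list(loglik = ll))

  W <- exp(S - rep(lse_n, each = R))  # per-(n, r) weights, sum to 1 per n
  ## observed net-best counts per respondent and option
  NB <- matrix(0, N, v)
  for (g in seq_len(d$b)) {
    NB[cbind(seq_len(N), ch$best[, g])] <- NB[cbind(seq_len(N), ch$best[, g])] + 1
    NB[cbind(seq_len(N), ch$worst[, g])] <- NB[cbind(seq_len(N), ch$worst[, g])] - 1
  }
  G <- NB[nrep, , drop = FALSE] - A   # per-(n, r) score wrt full beta
  WG <- W * G
  grad_mu <- colSums(WG)
  grad_sigma <- colSums(WG * Zfull)
  free <- setdiff(seq_len(v), ref)
  list(loglik = ll, grad = c(grad_mu[free], grad_sigma[free]))
}

#' Simulated maxdiff log-likelihood
#'
#' @param mu,sigma Full-length (v) mean and spread vectors with the
#'   reference entries 0.
#' @param panel A complete `bws_panel`.
#' @param draws Standard-normal draws: either an `N x R x (v-1)` array or
#'   an `(N*R) x (v-1)` respondent-major matrix (columns ordered as the
#'   non-reference options).
#' @param reference Reference option (label or index; default last item).
#' @return The simulated log-likelihood (a number). With `sigma = 0` it
#'   equals the pooled log-likelihood at `mu` exactly, for any draws.
#' @export
simulated_loglik <- function(mu, sigma, panel, draws, reference = NULL) {
  ref <- resolve_reference(reference, panel$design)
  Z <- draws_as_matrix(draws, n_respondents(panel))
  if (ncol(Z) != panel$design$v - 1)
    stop("draws must have v - 1 columns (one per non-reference option)")
  msl_core(mu, sigma, panel, Z, gradient = FALSE, ref = ref)$loglik
}

draws_as_matrix <- function(draws, N) {
  if (is.matrix(draws)) {
    if (nrow(draws) %% N != 0) stop("draw rows must be a multiple of N")
    return(draws)
  }
  if (length(dim(draws)) == 3) {
    dd <- dim(draws)
    if (dd[1] != N) stop("first draw dimension must be N")
    ## respondent-major flatten: row (n-1)*R + r  <-  draws[n, r, ]
    return(matrix(aperm(draws, c(2, 1, 3)), nrow = dd[1] * dd[2]))
  }
  stop("draws must be a matrix or 3-d array")
}

#' Fit the mixed-logit maxdiff model by maximum simulated likelihood
#'
#' BFGS over (mu, sigma) of the free options with the analytic simulated-
#' likelihood gradient; scrambled-Halton draws fixed by `seed` so the fit
#' is deterministic given `(R, seed)`. Standard errors from the inverse
#' observed information of the simulated log-likelihood.
#'
#' @param panel A complete `bws_panel`.
#' @param reference Reference option (default last item).
#' @param R Draws per respondent (default 500).
#' @param seed Seed for the Halton scrambling.
#' @param start Optional list with `mu`, `sigma` start values (full length).
#' @param maxit BFGS iteration cap.
#' @return A `bws_mixed` fit: `mu`, `sigma` (raw), `sigma_abs`, `se_mu`,
#'   `se_sigma`, `loglik`, `draw_settings`, `reference`, `convergence`.
#' @export
fit_mixed <- function(panel, reference = NULL, R = 500L, seed = 1L,
                      start = NULL, maxit = 400L) {
  if (R < 1) stop("R must be at least 1")
  d <- panel$design
  v <- d$v
  ref <- resolve_reference(reference, d)
  free <- setdiff(seq_len(v), ref)
  N <- n_respondents(panel)
  Z <- halton_normal_draws(N, R, v - 1, seed = seed)

  if (is.null(start)) {
    pooled <- fit_pooled(panel, reference = ref)
    start <- list(mu = pooled$beta, sigma = stats::setNames(rep(0.5, v), d$items))
    start$sigma[ref] <- 0
  }
  th0 <- c(start$mu[free], start$sigma[free])
  unpack <- function(th) {
    mu <- numeric(v); sg <- numeric(v)
    mu[free] <- th[seq_len(v - 1)]
    sg[free] <- th[v - 1 + seq_len(v - 1)]
    list(mu = mu, sigma = sg)
  }
  negll <- function(th) {
    p <- unpack(th)
    -msl_core(p$mu, p$sigma, panel, Z, gradient = FALSE, ref = ref)$loglik
  }
  neggr <- function(th) {
    p <- unpack(th)
    -msl_core(p$mu, p$sigma, panel, Z, gradient = TRUE, ref = ref)$grad
  }
  opt <- stats::optim(th0, negll, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (opt$convergence != 0)
    stop("mixed-logit estimation did not converge (optim code ",
         opt$convergence, ", ", opt$counts[1], " evaluations); ",
         "try more iterations or a different start")
  H <- stats::optimHess(opt$par, negll, neggr)
  cov <- tryCatch(solve(H),
                  error = function(e) matrix(NA_real_, 2 * (v - 1), 2 * (v - 1)))
  se_free <- sqrt(pmax(diag(cov), 0))
  p <- unpack(opt$par)
  mu <- stats::setNames(p$mu, d$items)
  sigma <- stats::setNames(p$sigma, d$items)
  se_mu <- se_sigma <- stats::setNames(rep(0, v), d$items)
  se_mu[free] <- se_free[seq_len(v - 1)]
  se_sigma[free] <- se_free[v - 1 + seq_len(v - 1)]
  structure(list(
    mu = mu, sigma = sigma, sigma_abs = abs(sigma),
    se_mu = se_mu, se_sigma = se_sigma, covariance = cov,
    loglik = -opt$value, n_obs = nrow(panel$cards),
    reference = d$items[ref], ref_index = ref,
    draw_settings = list(R = R, scheme = "scrambled-halton", seed = seed),
    convergence = list(code = opt$convergence, counts = opt$counts)
  ), class = c("bws_mixed", "bws_fit"))
}

#' Population shares of preference under the mixing distribution
#'
#' Draws beta ~ Normal(mu, diag(sigma^2)) and applies the share-of-
#' preference softmax per draw; reports the per-option mean share (summing
#' to 1) and the standard deviation across draws.
#'
#' @param model A `bws_mixed` fit (or a list with `mu`, `sigma`).
#' @param n_draws Monte-Carlo draws (default 10000).
#' @param seed Seed.
#' @return Data frame `option`, `mean_share`, `sd_share`.
#' @export
population_shares <- function(model, n_draws = 10000L, seed = 1L) {
  mu <- model$mu
  sg <- abs(model$sigma)
  v <- length(mu)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  Zd <- matrix(stats::rnorm(n_draws * v), n_draws, v)
  Bd <- sweep(Zd, 2, sg, "*") + matrix(mu, n_draws, v, byrow = TRUE)
  m <- Bd[cbind(seq_len(n_draws), max.col(Bd, ties.method = "first"))]
  E <- exp(Bd - m)
  Sh <- E / rowSums(E)
  data.frame(option = names(mu),
             mean_share = colMeans(Sh),
             sd_share = apply(Sh, 2, stats::sd))
}

#' @export
print.bws_mixed <- function(x, ...) {
  cat(sprintf("mixed-logit maxdiff fit: simulated logLik = %.2f (R = %d, %s)\n",
              x$loglik, x$draw_settings$R, x$draw_settings$scheme))
  tab <- data.frame(option = names(x$mu), mu = round(x$mu, 3),
                    se_mu = round(x$se_mu, 3),
                    sigma_abs = round(x$sigma_abs, 3),
                    se_sigma = round(x$se_sigma, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
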