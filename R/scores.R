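#' Counting-based best-worst scores
#'
#' Aggregate best/worst pick counts per option and the derived scales used
#' to summarise object-case best-worst data without a choice model:
#'
#' * `bw_score = (B - W) / (r * N)` — the standardized best-worst score,
#'   bounded in \[-1, 1\] (`r` = times the option appears per respondent,
#'   `N` = respondents);
#' * `sqrt_ratio = sqrt(B / W)` — the positive ratio scale;
#' * `std_ratio` — the sqrt ratio anchored at 100 for the top option;
#' * `rel_importance` — the sqrt ratio normalised to sum to 100 (percent).
#'
#' @name counting_scores
#' @keywords internal
NULL

#' Tally best and worst picks per option
#'
#' @param panel A complete, validated `bws_panel`.
#' @return Data frame `option`, `best`, `worst` with integer counts;
#'   both count columns sum to `N * b`.
#' @export
count_best_worst <- function(panel) {
  v <- panel$design$v
  data.frame(
    option = panel$design$items,
    best = tabulate(panel$cards$best, nbins = v),
    worst = tabulate(panel$cards$worst, nbins = v)
  )
}

#' Standardized best-worst score
#'
#' @param B,W Best and worst counts for one option (vectorised).
#' @param r Number of cards on which the option appears per respondent.
#' @param N Number of respondents.
#' @return `(B - W) / (r * N)`, in \[-1, 1\].
#' @examples
#' bw_score(17, 699, r = 4, N = 200)   # -0.8525
#' @export
bw_score <- function(B, W, r, N) {
  if (any(r * N <= 0)) stop("r * N must be positive")
  (B - W) / (r * N)
}

#' Ratio-scale scores from best/worst counts
#'
#' Builds the full counting-score table from per-option counts alone:
#' standardized best-worst score, sqrt(B/W) ratio, the ratio standardized to
#' 100 at the top option, relative importance summing to 100%, and rank
#' (1 = most important, ties broken by option order). Zero worst counts are
#' replaced by 0.5 (continuity correction) and flagged via the
#' `zero_worst` attribute.
#'
#' @param counts Data frame with columns `option`, `best`, `worst`
#'   (as from [count_best_worst()]).
#' @param r Appearances per respondent (scalar or per-option vector).
#' @param N Number of respondents.
#' @return A `bws_scores` data frame with columns `option`, `best`,
#'   `worst`, `bw_score`, `sqrt_ratio`, `std_ratio`, `rel_importance`,
#'   `rank`, plus attributes `wf_std_ratio` (= 100 / max sqrt ratio) and
#'   `wf_rel_importance` (= 100 / sum of sqrt ratios).
#' @examples
#' tab <- ratio_scores(milk_study_counts(), r = 4, N = 200)
#' attr(tab, "wf_rel_importance")   # 5.41
#' @export
ratio_scores <- function(counts, r, N) {
  B <- counts$best; W <- counts$worst
  zero_worst <- W == 0
  W_adj <- ifelse(zero_worst, 0.5, W)
  sqrt_ratio <- sqrt(B / W_adj)
  out <- data.frame(
    option = counts$option,
    best = B, worst = W,
    bw_score = bw_score(B, W, r, N),
    sqrt_ratio = sqrt_ratio,
    std_ratio = 100 * sqrt_ratio / max(sqrt_ratio),
    rel_importance = 100 * sqrt_ratio / sum(sqrt_ratio)
  )
  out$rank <- rank(-out$rel_importance, ties.method = "first")
  attr(out, "wf_std_ratio") <- 100 / max(sqrt_ratio)
  attr(out, "wf_rel_importance") <- 100 / sum(sqrt_ratio)
  attr(out, "zero_worst") <- counts$option[zero_worst]
  class(out) <- c("bws_scores", "data.frame")
  out
}

#' Per-respondent best-worst scores and their dispersion
#'
#' Each respondent's score for option o is `(B_n - W_n) / r` over their own
#' cards; its mean across respondents equals the aggregate `bw_score`. The
#' population standard deviation across respondents measures response
#' heterogeneity per option.
#'
#' @param panel A complete `bws_panel`.
#' @return List with `scores` (N x v matrix of individual scores) and `sd`
#'   (per-option population standard deviation).
#' @export
individual_scores <- function(panel) {
  v <- panel$design$v
  N <- n_respondents(panel)
  r <- panel$design$replication
  Bn <- matrix(0L, N, v)
  Wn <- matrix(0L, N, v)
  cds <- panel$cards
  for (i in seq_len(nrow(cds))) {
    Bn[cds$respondent[i], cds$best[i]] <- Bn[cds$respondent[i], cds$best[i]] + 1L
    Wn[cds$respondent[i], cds$worst[i]] <- Wn[cds$respondent[i], cds$worst[i]] + 1L
  }
  scores <- sweep(Bn - Wn, 2, r, "/")
  colnames(scores) <- panel$design$items
  sd_pop <- apply(scores, 2, function(x) sqrt(mean((x - mean(x))^2)))
  list(scores = scores, sd = sd_pop)
}

#' Full counting-score table for a panel
#'
#' Convenience wrapper: tallies the panel, computes [ratio_scores()] and
#' appends the individual-score standard deviation column.
#'
#' @param panel A complete `bws_panel`.
#' @return A `bws_scores` data frame (see [ratio_scores()]) with an extra
#'   `individual_sd` column.
#' @export
score_table <- function(panel) {
  counts <- count_best_worst(panel)
  r <- panel$design$replication
  if (length(unique(r)) != 1)
    stop("counting scores assume equal replication")
  out <- ratio_scores(counts, r = r[1], N = n_respondents(panel))
  isc <- individual_scores(panel)
  out$individual_sd <- unname(isc$sd)
  out[, c("option", "best", "worst", "bw_score", "individual_sd",
          "sqrt_ratio", "std_ratio", "rel_importance", "rank")]
}

#' @export
print.bws_scores <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & !(names(y) %in% c("best", "worst", "rank"))
  y[num] <- lapply(y[num], round, digits)
  if ("rel_importance" %in% names(y))
    y$rel_importance <- sprintf("%.1f%%", as.numeric(x$rel_importance))
  print(y, row.names = FALSE)
  cat(sprintf("weighting factors: std ratio %.2f, relative importance %.2f\n",
              attr(x, "wf_std_ratio"), attr(x, "wf_rel_importance")))
  invisible(x)
}
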