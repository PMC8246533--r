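#' Best-worst response panels
#'
#' A `bws_panel` bundles a `bws_design` with the responses of `N`
#' respondents: for each card (block) the item picked as *best* (most
#' likely) and the item picked as *worst* (least likely). Internally cards
#' are a data frame of integer indices (`respondent`, `block`, `best`,
#' `worst`); all I/O uses item labels. Optional per-respondent covariates
#' (income tier, head gender/age/education, ...) ride along for class
#' profiling.
#'
#' @param design A `bws_design`.
#' @param cards Data frame with integer columns `respondent`, `block`,
#'   `best`, `worst` (item indices into `design$items`).
#' @param respondents Character vector of respondent identifiers.
#' @param covariates Optional data frame keyed by `respondent_id`.
#' @param complete If `TRUE` (default) every respondent must answer every
#'   block exactly once; set `FALSE` to accept incomplete panels, in which
#'   case missing cards are simply absent (card-wise exclusion).
#' @return A validated `bws_panel`.
#' @export
bws_panel <- function(design, cards, respondents = NULL, covariates = NULL,
                      complete = TRUE) {
  cards <- as.data.frame(cards)
  stopifnot(all(c("respondent", "block", "best", "worst") %in% names(cards)))
  if (is.null(respondents))
    respondents <- sort(unique(cards$respondent))
  cards$respondent <- match(cards$respondent, respondents)
  panel <- structure(
    list(design = design, cards = cards, respondents = as.character(respondents),
         covariates = covariates, complete = complete),
    class = "bws_panel"
  )
  validate_panel(panel)
}

#' Validate a response panel against its design
#'
#' Checks that every card's best and worst picks are distinct members of
#' the card's shown set, that no (respondent, card) is duplicated, and —
#' for complete panels — that every respondent answered every block.
#'
#' @param panel A `bws_panel`.
#' @return The panel, invisibly usable; errors name the offending
#'   respondent and card.
#' @export
validate_panel <- function(panel) {
  d <- panel$design
  cards <- panel$cards
  for (i in seq_len(nrow(cards))) {
    rw <- cards[i, ]
    shown <- d$blocks[[rw$block]]
    who <- sprintf("respondent '%s', card C%d",
                   panel$respondents[rw$respondent], rw$block)
    if (rw$best == rw$worst)
      stop("best equals worst for ", who)
    if (!(rw$best %in% shown) || !(rw$worst %in% shown))
      stop("choice not among the shown options for ", who)
  }
  key <- paste(cards$respondent, cards$block)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("duplicate card: respondent '%s', card C%d",
                 panel$respondents[cards$respondent[i]], cards$block[i]))
  }
  if (isTRUE(panel$complete)) {
    expected <- length(panel$respondents) * d$b
    if (nrow(cards) != expected)
      stop("incomplete panel: ", nrow(cards), " cards, expected ", expected,
           " (pass complete = FALSE to allow card-wise exclusion)")
  }
  panel
}

#' @export
print.bws_panel <- function(x, ...) {
  cat(sprintf("bws_panel: %d respondents, %d cards (%s)\n",
              length(x$respondents), nrow(x$cards),
              if (isTRUE(x$complete)) "complete" else "possibly incomplete"))
  if (!is.null(x$covariates))
    cat(sprintf("  covariates: %s\n",
                paste(setdiff(names(x$covariates), "respondent_id"),
                      collapse = ", ")))
  invisible(x)
}

n_respondents <- function(panel) length(panel$respondents)

#' Expand a card into its maxdiff pair choice set
#'
#' The maxdiff model treats a best/worst answer on a card showing J items
#' as one choice among the J*(J-1) ordered (best-candidate, worst-candidate)
#' pairs. Pairs are enumerated in lexicographic order of (i, j).
#'
#' @param shown Integer or character vector of the card's shown items
#'   (length J >= 2).
#' @return A two-column matrix (`best`, `worst`) of all ordered pairs of
#'   distinct shown items.
#' @examples
#' expand_pairs(c(1, 3, 5, 7))   # 12 ordered pairs
#' @export
expand_pairs <- function(shown) {
  J <- length(shown)
  if (J < 2) stop("a card needs at least 2 shown items")
  idx <- expand.grid(worst = seq_len(J), best = seq_len(J))
  idx <- idx[idx$best != idx$worst, c("best", "worst")]
  idx <- idx[order(idx$best, idx$worst), ]
  m <- cbind(best = shown[idx$best], worst = shown[idx$worst])
  rownames(m) <- NULL
  m
}

#' Read / write a response panel as CSV
#'
#' Canonical layout: header `respondent_id,card_id,best,worst`, one row per
#' card, sorted by respondent then card; `best`/`worst` are item labels and
#' `card_id` is `C<block>`. An optional covariates CSV keyed by
#' `respondent_id` is merged in. Writing then reading reproduces the panel
#' byte-stably.
#'
#' @param path Responses CSV path.
#' @param design The `bws_design` the responses were collected under.
#' @param covariates_path Optional covariates CSV path.
#' @param complete Passed to [bws_panel()].
#' @return `read_panel` returns a `bws_panel`; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path, design, covariates_path = NULL, complete = TRUE) {
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("respondent_id", "card_id", "best", "worst") %in% names(df)))
  block <- as.integer(sub("^C", "", df$card_id))
  best <- match(df$best, design$items)
  worst <- match(df$worst, design$items)
  bad <- which(is.na(best) | is.na(worst) | is.na(block) |
                 block < 1 | block > design$b)
  if (length(bad))
    stop("unresolvable labels/card ids at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  covariates <- NULL
  if (!is.null(covariates_path)) {
    covariates <- utils::read.csv(covariates_path, colClasses = "character")
    stopifnot("respondent_id" %in% names(covariates))
  }
  bws_panel(design,
            data.frame(respondent = df$respondent_id, block = block,
                       best = best, worst = worst),
            respondents = sort(unique(df$respondent_id)),
            covariates = covariates, complete = complete)
}

#' @rdname read_panel
#' @param panel A `bws_panel`.
#' @export
write_panel <- function(panel, path, covariates_path = NULL) {
  d <- panel$design
  cards <- panel$cards[order(panel$cards$respondent, panel$cards$block), ]
  out <- data.frame(
    respondent_id = panel$respondents[cards$respondent],
    card_id = paste0("C", cards$block),
    best = d$items[cards$best],
    worst = d$items[cards$worst]
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariates_path) && !is.null(panel$covariates))
    utils::write.csv(panel$covariates, covariates_path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

## per-option appearance count for one respondent's complete panel equals the
## design replication; across a complete panel each option is seen N * r times
option_appearances <- function(panel) {
  n_respondents(panel) * panel$design$replication
}
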