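#' Best-worst choice-card designs
#'
#' A `bws_design` holds the block structure used to build best-worst choice
#' cards: `v` items arranged into `b` blocks (cards) of `k` distinct items
#' each, with equal replication `r = b*k/v`. Perfect balance (every pair of
#' items co-occurring equally often) requires `r*(k-1)` divisible by `v-1`;
#' when it is not, the design is *nearly* balanced and the generator minimises
#' the spread of pairwise co-occurrence counts instead.
#'
#' @name bws_design
#' @keywords internal
NULL

new_bws_design <- function(items, blocks) {
  v <- length(items)
  blocks <- lapply(blocks, function(bl) sort(as.integer(bl)))
  design <- structure(
    list(items = items, blocks = blocks, v = v, b = length(blocks),
         k = length(blocks[[1]])),
    class = "bws_design"
  )
  design$replication <- design_replication(design)
  design$concurrence <- concurrence_matrix(design)
  validate_design(design)
  design
}

validate_design <- function(design) {
  v <- design$v; k <- design$k; b <- design$b
  for (bl in design$blocks) {
    if (length(bl) != k || anyDuplicated(bl) || any(bl < 1L | bl > v))
      stop("invalid block: expected ", k, " distinct items in 1..", v)
  }
  lam <- design$concurrence
  stopifnot(isSymmetric(lam), all(diag(lam) == design$replication))
  off_total <- sum(lam[upper.tri(lam)])
  if (off_total != b * k * (k - 1) / 2)
    stop("concurrence total does not match b*k*(k-1)/2")
  invisible(design)
}

design_replication <- function(design) {
  tabulate(unlist(design$blocks), nbins = design$v)
}

#' Incidence matrix of a block design
#'
#' @param design A `bws_design`.
#' @return A `v x b` 0/1 matrix with entry (i, g) = 1 when item i is in
#'   block g. Column sums equal the block size `k`; row sums equal the
#'   per-item replication.
#' @export
incidence_matrix <- function(design) {
  N <- matrix(0L, design$v, design$b,
              dimnames = list(design$items, paste0("C", seq_len(design$b))))
  for (g in seq_len(design$b)) N[design$blocks[[g]], g] <- 1L
  N
}

#' Pairwise co-occurrence (concurrence) matrix
#'
#' @param design A `bws_design`.
#' @return A symmetric `v x v` integer matrix; off-diagonal entry (i, j)
#'   counts the blocks containing both items, the diagonal holds the
#'   replication counts.
#' @export
concurrence_matrix <- function(design) {
  N <- incidence_matrix(design)
  lam <- N %*% t(N)
  storage.mode(lam) <- "integer"
  lam
}

off_diag_variance <- function(lam) {
  stats::var(lam[upper.tri(lam)])
}

#' Generate a (nearly) balanced incomplete block design
#'
#' Constructs `b` choice cards of `k` distinct items over `v` items with
#' equal replication `r = b*k/v`, then hill-climbs on pairwise item exchanges
#' to minimise the variance of the off-diagonal concurrence counts. When a
#' perfect BIBD exists for (v, b, k) the search typically finds it; otherwise
#' it returns a near-BIBD whose co-occurrence counts are as even as the
#' exchange search achieves.
#'
#' @param v Number of items.
#' @param b Number of blocks (cards).
#' @param k Block size (items shown per card); `v >= k >= 2`.
#' @param seed Integer seed; the construction is deterministic given
#'   (v, b, k, seed).
#' @param max_iter Exchange-search budget across restarts.
#' @param items Optional character labels (default `"O1".."Ov"`).
#' @return A `bws_design` with components `items`, `blocks` (1-based sorted
#'   index sets), `replication` and `concurrence`.
#' @examples
#' d <- generate_design(9, 9, 4, seed = 1)
#' d$replication                      # all 4
#' average_pairwise_frequency(d)      # 1.5
#' @export
generate_design <- function(v, b, k, seed = 1L, max_iter = 20000L,
                            items = paste0("O", seq_len(v))) {
  if (k < 2 || v < k) stop("need v >= k >= 2")
  if ((b * k) %% v != 0)
    stop("infeasible: b*k = ", b * k, " is not divisible by v = ", v,
         "; equal replication is unattainable")
  r <- (b * k) %/% v
  set.seed(as.integer(seed) %% .Machine$integer.max)

  ## best attainable spread of the off-diagonal concurrences: total
  ## T = b*k*(k-1)/2 split over v*(v-1)/2 pairs as floor/ceil of the mean
  n_pairs <- v * (v - 1) / 2
  total <- b * k * (k - 1) / 2
  lo <- floor(total / n_pairs); n_hi <- total - lo * n_pairs
  target_var <- stats::var(c(rep(lo, n_pairs - n_hi), rep(lo + 1, n_hi)))

  best_blocks <- NULL
  best_var <- Inf
  iter_used <- 0L
  while (iter_used < max_iter) {
    blocks <- random_equal_replication_blocks(v, b, k, r)
    if (is.null(blocks)) { iter_used <- iter_used + b; next }
    res <- exchange_improve(blocks, v, max_iter - iter_used)
    iter_used <- iter_used + res$iter
    if (res$var < best_var) { best_var <- res$var; best_blocks <- res$blocks }
    if (best_var <= target_var + 1e-12) break
  }
  if (is.null(best_blocks))
    stop("max_iter exhausted without an equal-replication design")
  new_bws_design(items, best_blocks)
}

## deal a shuffled multiset (each item r times) into b blocks of k, repairing
## within-block duplicates by cross-block swaps; NULL if repair fails
random_equal_replication_blocks <- function(v, b, k, r) {
  pool <- sample(rep(seq_len(v), r))
  m <- matrix(pool, nrow = k, ncol = b)
  for (tries in 1:200) {
    dup <- which(apply(m, 2, anyDuplicated) > 0)
    if (!length(dup)) return(lapply(seq_len(b), function(g) m[, g]))
    g <- dup[1]
    i <- anyDuplicated(m[, g])
    swapped <- FALSE
    for (h in sample(setdiff(seq_len(b), g))) {
      for (j in sample(k)) {
        if (!(m[j, h] %in% m[, g]) && !(m[i, g] %in% m[, h])) {
          tmp <- m[j, h]; m[j, h] <- m[i, g]; m[i, g] <- tmp
          swapped <- TRUE; break
        }
      }
      if (swapped) break
    }
    if (!swapped) return(NULL)
  }
  NULL
}

## pairwise item-exchange hill climbing on the off-diagonal concurrence
## variance; swapping items between two blocks preserves replication
exchange_improve <- function(blocks, v, budget) {
  b <- length(blocks)
  lam <- concurrence_matrix(new_minimal_design(blocks, v))
  cur <- off_diag_variance(lam)
  iter <- 0L
  improved <- TRUE
  while (improved && iter < budget) {
    improved <- FALSE
    for (g in sample(b)) {
      for (h in sample(b)) {
        if (h == g) next
        for (x in blocks[[g]]) {
          for (y in blocks[[h]]) {
            iter <- iter + 1L
            if (y %in% blocks[[g]] || x %in% blocks[[h]] || x == y) next
            cand <- blocks
            cand[[g]] <- c(setdiff(cand[[g]], x), y)
            cand[[h]] <- c(setdiff(cand[[h]], y), x)
            new_lam <- concurrence_matrix(new_minimal_design(cand, v))
            new_var <- off_diag_variance(new_lam)
            if (new_var < cur - 1e-12) {
              blocks <- cand; cur <- new_var; improved <- TRUE
            }
            if (iter >= budget) break
          }
          if (iter >= budget) break
        }
        if (iter >= budget) break
      }
      if (iter >= budget) break
    }
  }
  list(blocks = blocks, var = cur, iter = iter)
}

new_minimal_design <- function(blocks, v) {
  structure(list(items = seq_len(v), blocks = blocks, v = v,
                 b = length(blocks), k = length(blocks[[1]])),
            class = "bws_design")
}

#' Average pairwise co-occurrence frequency
#'
#' Mean of the off-diagonal concurrence counts; equals the closed form
#' `b*k*(k-1) / (v*(v-1))` for any design with `b` blocks of size `k`.
#'
#' @param design A `bws_design`.
#' @return A single number.
#' @export
average_pairwise_frequency <- function(design) {
  lam <- design$concurrence
  mean(lam[upper.tri(lam)])
}

#' D-efficiency of a block design
#'
#' Efficiency of the within-block information matrix
#' `C = diag(r) - N N' / k` relative to a perfect BIBD with the same
#' (v, b, k): `100 * gm / (v * lambda_bar / k)` where `gm` is the geometric
#' mean of the `v - 1` nonzero eigenvalues of `C` and
#' `lambda_bar = r*(k-1)/(v-1)` is the average concurrence. Equals 100
#' exactly iff every pair of items co-occurs `lambda_bar` times.
#'
#' @param design A `bws_design` with equal replication.
#' @return Percent efficiency in (0, 100].
#' @export
design_efficiency <- function(design) {
  r <- design$replication
  if (length(unique(r)) != 1)
    stop("design efficiency is defined here only for equal replication")
  r <- r[1]; v <- design$v; k <- design$k
  N <- incidence_matrix(design)
  C <- diag(r, v) - N %*% t(N) / k
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)[seq_len(v - 1)]
  if (any(ev <= 1e-10)) return(0)
  lambda_bar <- r * (k - 1) / (v - 1)
  100 * exp(mean(log(ev))) / (v * lambda_bar / k)
}

#' @export
print.bws_design <- function(x, ...) {
  cat(sprintf("bws_design: v = %d items, b = %d blocks of k = %d\n",
              x$v, x$b, x$k))
  cat(sprintf("  replication: %s\n", paste(x$replication, collapse = " ")))
  cat(sprintf("  mean pairwise frequency: %.3f; D-efficiency: %.1f%%\n",
              average_pairwise_frequency(x),
              tryCatch(design_efficiency(x), error = function(e) NA)))
  for (g in seq_len(x$b))
    cat(sprintf("  C%d: %s\n", g, paste(x$items[x$blocks[[g]]], collapse = ", ")))
  invisible(x)
}

#' Read / write a design file
#'
#' Designs are serialised as JSON with fields `version`, `v`, `b`, `k`,
#' `item_labels` and `blocks` (lists of item labels).
#'
#' @param design A `bws_design`.
#' @param path File path.
#' @return `read_design` returns a `bws_design`; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path) {
  obj <- list(
    version = 1L, v = design$v, b = design$b, k = design$k,
    item_labels = design$items,
    blocks = lapply(design$blocks, function(bl) design$items[bl])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- obj$item_labels
  if (is.matrix(obj$blocks))
    obj$blocks <- lapply(seq_len(nrow(obj$blocks)), function(i) obj$blocks[i, ])
  blocks <- lapply(obj$blocks, function(bl) match(unlist(bl), items))
  if (anyNA(unlist(blocks))) stop("design file contains unknown item labels")
  new_bws_design(items, blocks)
}
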