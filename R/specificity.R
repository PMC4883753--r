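#' Expressed-gene filter
#'
#' A gene counts as expressed when its FPKM exceeds a floor in at least one
#' time point. The comparison is strict (`>`), so the conventional floor of
#' 1 FPKM excludes genes that never rise above 1.
#'
#' @param x an [expression_matrix()]
#' @param floor FPKM threshold (default 1)
#' @return character vector of expressed gene ids, in matrix order
#' @export
filter_expressed <- function(x, floor = 1) {
  stopifnot(inherits(x, "expr_matrix"), floor >= 0)
  mx <- apply(x$fpkm, 1L, max)
  rownames(x$fpkm)[mx > floor]
}

#' Stage-specificity profile
#'
#' For each gene, its FPKM values are summed over the time course and each
#' time point's share of that sum is recorded. A gene placing more than 90%
#' of its summed FPKM at one time point is a strong candidate for a
#' stage-specific role (e.g. envelope deposition for the earliest stage).
#' Genes with zero total FPKM carry undefined (NA) fractions and are
#' excluded from downstream counts.
#'
#' @param x an [expression_matrix()]
#' @param universe optional subset of gene ids (default: expressed genes by
#'   [filter_expressed()] with floor 1)
#' @param min_total optional minimum summed-FPKM floor applied to the
#'   universe (default 0 = no floor)
#' @return list of class `specificity_profile`: `fraction` (genes x times),
#'   `total_fpkm`, `peak_time`, `peak_fraction`, `times`
#' @export
specificity_fractions <- function(x, universe = NULL, min_total = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(universe)) universe <- filter_expressed(x)
  if (!all(universe %in% rownames(x$fpkm)))
    stop("universe contains genes absent from the matrix")
  m <- x$fpkm[universe, , drop = FALSE]
  tot <- rowSums(m)
  keep <- tot > min_total
  frac <- m / tot           # rows with tot == 0 become NaN
  frac[tot == 0, ] <- NA_real_
  pk <- integer(nrow(m))
  pk[tot > 0] <- apply(frac[tot > 0, , drop = FALSE], 1L, which.max)
  structure(list(
    fraction = frac[keep, , drop = FALSE],
    total_fpkm = tot[keep],
    peak_time = x$times[pk[keep]],
    peak_fraction = apply(frac[keep, , drop = FALSE], 1L,
                          function(r) if (anyNA(r)) NA_real_ else max(r)),
    times = x$times), class = "specificity_profile")
}

#' Count stage-specific genes per time point
#'
#' Genes whose fraction at a time point strictly exceeds `alpha`. At
#' `alpha >= 0.5` each gene can qualify at no more than one time point.
#'
#' @param profile a [specificity_fractions()] result
#' @param alpha fraction threshold in (0, 1]
#' @return list with `counts` (named by time) and `genes` (list of id
#'   vectors, named by time)
#' @export
count_stage_specific <- function(profile, alpha = 0.9) {
  stopifnot(inherits(profile, "specificity_profile"),
            alpha > 0, alpha <= 1)
  fr <- profile$fraction
  genes <- lapply(seq_along(profile$times), function(j) {
    hit <- !is.na(fr[, j]) & fr[, j] > alpha
    rownames(fr)[hit]
  })
  names(genes) <- as.character(profile$times)
  list(counts = stats::setNames(lengths(genes), names(genes)),
       genes = genes)
}

#' Union of the top-n most highly expressed genes per time point
#'
#' Per time point the `n` genes with the highest FPKM are taken (ties broken
#' by descending total FPKM, then lexicographic id) and the per-time sets
#' are unioned.
#'
#' @param x an [expression_matrix()]
#' @param n genes per time point (default 20)
#' @return list: `union` (sorted id vector) and `per_time` (list of the n-gene
#'   sets, named by time)
#' @export
top_expressed_union <- function(x, n = 20) {
  stopifnot(inherits(x, "expr_matrix"), n >= 1)
  ids <- rownames(x$fpkm)
  tot <- rowSums(x$fpkm)
  n <- min(n, length(ids))
  per_time <- lapply(seq_along(x$times), function(j) {
    ord <- order(-x$fpkm[, j], -tot, ids)
    ids[ord[seq_len(n)]]
  })
  names(per_time) <- as.character(x$times)
  list(union = sort(unique(unlist(per_time))), per_time = per_time)
}

#' Shortest prefix of genes carrying a share of a subset's total FPKM
#'
#' Genes of `subset` are sorted by descending total FPKM and the shortest
#' prefix whose summed totals strictly exceed `share` of the subset total is
#' returned. Used, e.g., to show how few cuticle-protein genes dominate the
#' cuticle-protein transcript pool.
#'
#' @param x an [expression_matrix()]
#' @param subset gene ids (must have positive total FPKM overall)
#' @param share fraction in (0, 1)
#' @return character vector: the ordered prefix
#' @export
cumulative_contributors <- function(x, subset, share) {
  stopifnot(inherits(x, "expr_matrix"), share > 0, share < 1,
            length(subset) > 0)
  subset <- intersect(subset, rownames(x$fpkm))
  tot <- rowSums(x$fpkm[subset, , drop = FALSE])
  if (sum(tot) == 0) stop("subset has zero total FPKM")
  ord <- order(-tot, subset)
  cum <- cumsum(tot[ord])
  k <- which(cum > share * sum(tot))[1L]
  subset[ord][seq_len(k)]
}

#' Fold changes between neighboring time points
#'
#' For each gene and each adjacent time pair, fold = (max + pseudo) /
#' (min + pseudo) with direction. With `pseudo = 0`: 0 vs 0 gives fold 1
#' (no change) and 0 vs positive gives +Inf, which satisfies any finite
#' threshold.
#'
#' @param x an [expression_matrix()]
#' @param pseudo small FPKM offset added to numerator and denominator
#'   (default 0)
#' @return list with `fold` (genes x pairs matrix, values >= 1),
#'   `direction` (same shape; "rising", "falling" or "flat") and `pairs`
#'   (two-column matrix of time labels)
#' @export
neighbor_fold_change <- function(x, pseudo = 0) {
  stopifnot(inherits(x, "expr_matrix"), pseudo >= 0)
  pr <- neighbor_pairs(x$times)
  np <- nrow(pr)
  fold <- matrix(NA_real_, nrow(x$fpkm), np)
  dir <- matrix("flat", nrow(x$fpkm), np)
  for (j in seq_len(np)) {
    a <- x$fpkm[, j]; b <- x$fpkm[, j + 1L]
    fold[, j] <- fold_ratio(a, b, pseudo)
    dir[, j] <- ifelse(b > a, "rising", ifelse(b < a, "falling", "flat"))
  }
  pn <- paste(pr[, 1L], pr[, 2L], sep = "/")
  dimnames(fold) <- dimnames(dir) <- list(rownames(x$fpkm), pn)
  list(fold = fold, direction = dir, pairs = pr)
}

# (max+pseudo)/(min+pseudo); 0/0 -> 1, x/0 -> Inf when pseudo = 0
fold_ratio <- function(a, b, pseudo = 0) {
  hi <- pmax(a, b) + pseudo
  lo <- pmin(a, b) + pseudo
  out <- ifelse(hi == 0, 1, hi / lo)
  out[hi > 0 & lo == 0] <- Inf
  out
}
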