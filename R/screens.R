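#' Fold-change category table over significant genes
#'
#' For every neighboring time-point pair, counts the genes with a
#' significant expression difference (q < `q_cut`) and, among those, the
#' genes whose fold change strictly exceeds each threshold (categories are
#' nested: every >100-fold gene is also a >10-fold gene). The fold used is
#' the one reported in the differential-expression table when present;
#' otherwise it is recomputed from the FPKM matrix with no pseudocount.
#'
#' @param x an [expression_matrix()]
#' @param de a `de_result` (see [read_de_table()]) covering every neighbor
#'   pair of the grid
#' @param q_cut significance cutoff (default 0.05)
#' @param thresholds fold thresholds, strict (default c(10, 100))
#' @return data.frame: t1, t2, n_significant, then one count column per
#'   threshold
#' @export
fold_category_table <- function(x, de, q_cut = 0.05, thresholds = c(10, 100)) {
  stopifnot(inherits(x, "expr_matrix"))
  pr <- neighbor_pairs(x$times)
  nfc <- NULL
  rows <- lapply(seq_len(nrow(pr)), function(j) {
    t1 <- pr[j, 1L]; t2 <- pr[j, 2L]
    rec <- de[(de$t1 == t1 & de$t2 == t2) | (de$t1 == t2 & de$t2 == t1), ,
              drop = FALSE]
    if (nrow(de) > 0 && nrow(rec) == 0)
      stop("DE table has no records for neighbor pair ", t1, "/", t2)
    sig <- rec[rec$q < q_cut, , drop = FALSE]
    fold <- sig$fold
    if (anyNA(fold)) {
      if (is.null(nfc)) nfc <<- neighbor_fold_change(x)$fold
      miss <- is.na(fold)
      fold[miss] <- nfc[sig$gene[miss], j]
    }
    counts <- vapply(thresholds, function(th) sum(fold > th), 0L)
    c(n_significant = nrow(sig), stats::setNames(counts,
                                                 paste0("n_over_", thresholds)))
  })
  out <- data.frame(t1 = pr[, 1L], t2 = pr[, 2L], do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Two-stage screen for candidate regulatory transcription factors
#'
#' Stage 1 keeps the annotated DNA-binding / PolII-regulatory genes reaching
#' an FPKM of at least `min_fpkm` in some time point; stage 2 keeps, of
#' those, the genes whose expression differs at least `min_fold`-fold
#' between some pair of neighboring time points. Both cutoffs are inclusive
#' (>=). Stage-2 genes are the candidates for driving the staged cuticle
#' deposition program.
#'
#' @param x an [expression_matrix()]
#' @param tf_genes character vector of annotated TF gene ids
#' @param min_fpkm expression floor (default 30)
#' @param min_fold neighbor fold floor (default 4)
#' @return list: `stage1` (ids passing the expression floor) and `stage2`
#'   (data.frame gene, max_fold, sorted by descending fold)
#' @export
tf_candidates <- function(x, tf_genes, min_fpkm = 30, min_fold = 4) {
  stopifnot(inherits(x, "expr_matrix"), min_fpkm > 0, min_fold > 0)
  if (length(tf_genes) == 0) {
    warning("empty TF gene list")
    return(list(stage1 = character(),
                stage2 = data.frame(gene = character(), max_fold = numeric())))
  }
  tf <- intersect(tf_genes, rownames(x$fpkm))
  mx <- apply(x$fpkm[tf, , drop = FALSE], 1L, max)
  stage1 <- tf[mx >= min_fpkm]
  if (length(stage1) == 0)
    return(list(stage1 = stage1,
                stage2 = data.frame(gene = character(), max_fold = numeric())))
  folds <- neighbor_fold_change(x)$fold[stage1, , drop = FALSE]
  mf <- apply(folds, 1L, max)
  keep <- mf >= min_fold
  stage2 <- data.frame(gene = stage1[keep], max_fold = mf[keep],
                       row.names = NULL)
  stage2 <- stage2[order(-stage2$max_fold, stage2$gene), , drop = FALSE]
  rownames(stage2) <- NULL
  list(stage1 = stage1, stage2 = stage2)
}
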