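#' Per-gene isoform fractions at each time point
#'
#' Each isoform's FPKM divided by its gene's total at that time point.
#' Where the gene total is zero the fractions are undefined (NA).
#'
#' @param iso an [isoform_matrix()]
#' @return matrix (isoforms x times) of fractions in \[0, 1\] or NA
#' @export
isoform_fractions <- function(iso) {
  stopifnot(inherits(iso, "isoform_matrix"))
  totals <- rowsum(iso$fpkm, group = iso$gene)
  denom <- totals[iso$gene, , drop = FALSE]
  fr <- iso$fpkm / denom
  fr[denom == 0] <- NA_real_
  rownames(fr) <- rownames(iso$fpkm)
  fr
}

#' Detect dominant-isoform switches between neighboring time points
#'
#' A switch is reported for gene g at the adjacent pair (t1, t2) when the
#' identity of the dominant (highest-FPKM) isoform changes from t1 to t2,
#' both dominants have FPKM >= `min_fpkm` at the time point where they
#' dominate, and each dominant's fraction of the gene total changes by at
#' least `min_delta` across the pair. This operational definition (with its
#' default floors) is the package's stated switch criterion; it is fully
#' threshold-exposed and deterministic.
#'
#' @param iso an [isoform_matrix()]
#' @param min_fpkm absolute expression floor on each dominant isoform
#'   (default 1)
#' @param min_delta minimum fraction change for both isoforms (default 0.25)
#' @return data.frame of events: gene, t1, t2, isoform_down (dominant
#'   before), isoform_up (dominant after), the four fractions, min_fpkm
#'   involved. Zero rows when nothing switches.
#' @export
detect_switches <- function(iso, min_fpkm = 1, min_delta = 0.25) {
  stopifnot(inherits(iso, "isoform_matrix"),
            min_fpkm >= 0, min_delta >= 0)
  fr <- isoform_fractions(iso)
  pr <- neighbor_pairs(iso$times)
  ev <- list()
  for (g in unique(iso$gene)) {
    rows <- which(iso$gene == g)
    if (length(rows) < 2L) next
    sub <- iso$fpkm[rows, , drop = FALSE]
    subf <- fr[rows, , drop = FALSE]
    dom <- apply(sub, 2L, which.max)    # ties: first (lowest) index
    for (j in seq_len(nrow(pr))) {
      d1 <- dom[j]; d2 <- dom[j + 1L]
      if (d1 == d2) next
      if (colSums(sub)[j] == 0 || colSums(sub)[j + 1L] == 0) next
      out_id <- rownames(sub)[d1]; in_id <- rownames(sub)[d2]
      if (sub[d1, j] < min_fpkm || sub[d2, j + 1L] < min_fpkm) next
      d_out <- subf[d1, j] - subf[d1, j + 1L]
      d_in <- subf[d2, j + 1L] - subf[d2, j]
      if (d_out < min_delta || d_in < min_delta) next
      ev[[length(ev) + 1L]] <- data.frame(
        gene = g, t1 = pr[j, 1L], t2 = pr[j, 2L],
        isoform_down = out_id, isoform_up = in_id,
        frac_down_before = subf[d1, j], frac_down_after = subf[d1, j + 1L],
        frac_up_before = subf[d2, j], frac_up_after = subf[d2, j + 1L],
        min_fpkm_involved = min(sub[d1, j], sub[d2, j + 1L]))
    }
  }
  if (length(ev) == 0)
    return(data.frame(gene = character(), t1 = numeric(), t2 = numeric(),
                      isoform_down = character(), isoform_up = character(),
                      frac_down_before = numeric(), frac_down_after = numeric(),
                      frac_up_before = numeric(), frac_up_after = numeric(),
                      min_fpkm_involved = numeric()))
  out <- do.call(rbind, ev)
  out <- out[order(out$gene, out$t1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count isoforms changing in abundance across the time course
#'
#' For each isoform, the maximal fold change between any two time points
#' (not only neighbors): (max + pseudo) / (min + pseudo), with 0/0 -> 1 and
#' positive/0 -> Inf when `pseudo = 0`.
#'
#' @param iso an [isoform_matrix()]
#' @param fold counting threshold, inclusive (default 10)
#' @param pseudo FPKM offset (default 0)
#' @return list: `per_isoform` (data.frame isoform, gene, max_fold),
#'   `n_changed` (isoforms with max_fold >= `fold`)
#' @export
count_isoform_changes <- function(iso, fold = 10, pseudo = 0) {
  stopifnot(inherits(iso, "isoform_matrix"), fold >= 1, pseudo >= 0)
  hi <- apply(iso$fpkm, 1L, max)
  lo <- apply(iso$fpkm, 1L, min)
  mf <- fold_ratio(hi, lo, pseudo)
  per <- data.frame(isoform = rownames(iso$fpkm),
                    gene = unname(iso$gene[rownames(iso$fpkm)]),
                    max_fold = mf, row.names = NULL)
  list(per_isoform = per, n_changed = sum(mf >= fold))
}

#' Correlation of two isoform trajectories
#'
#' Pearson correlation of the log10(FPKM + 1)-transformed trajectories of
#' two isoforms — used to quantify cross-gene isoform co-expression (e.g.
#' the coordinated mwh-RA / CG14257-RC pair). A constant trajectory has no
#' defined correlation and yields NA.
#'
#' @param iso an [isoform_matrix()]
#' @param a,b isoform ids
#' @return correlation in \[-1, 1\], or NA if either trajectory is constant
#' @export
trajectory_correlation <- function(iso, a, b) {
  stopifnot(inherits(iso, "isoform_matrix"))
  for (id in c(a, b))
    if (!id %in% rownames(iso$fpkm)) stop("unknown isoform: ", id)
  if (length(iso$times) < 3L) stop("need at least 3 time points")
  x <- log10(iso$fpkm[a, ] + 1)
  y <- log10(iso$fpkm[b, ] + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
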