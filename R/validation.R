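#' Construct a qPCR plate
#'
#' Ct values for target genes and an endogenous control gene across samples
#' and replicates, plus the calibrator sample against which relative
#' quantification is expressed.
#'
#' @param wells data.frame with columns sample, target, replicate, ct
#' @param control_gene the endogenous control target (e.g. an evenly
#'   expressed gene such as Xbp1)
#' @param calibrator the calibrator sample id (RQ = 1 by definition)
#' @return list of class `qpcr_plate`
#' @export
qpcr_plate <- function(wells, control_gene, calibrator) {
  need <- c("sample", "target", "replicate", "ct")
  if (!all(need %in% names(wells)))
    stop("wells needs columns sample, target, replicate, ct")
  if (!control_gene %in% wells$target)
    stop("control gene ", control_gene, " absent from plate")
  if (!calibrator %in% wells$sample)
    stop("calibrator sample ", calibrator, " absent from plate")
  for (s in unique(wells$sample))
    if (!any(wells$sample == s & wells$target == control_gene))
      stop("missing control wells for sample ", s)
  structure(list(wells = wells, control_gene = control_gene,
                 calibrator = calibrator), class = "qpcr_plate")
}

#' Relative quantification (delta-delta-Ct) of a qPCR plate
#'
#' Per replicate, dCt = Ct_target - Ct_control (matched by replicate
#' index); ddCt subtracts the calibrator's mean dCt; RQ = 2^(-ddCt). The
#' reported RQ per sample is 2^(-mean ddCt) — the geometric mean of the
#' replicate RQs, the convention of qPCR instrument software — so the
#' calibrator's RQ is exactly 1. The SD is the standard deviation of the
#' per-replicate RQs.
#'
#' @param plate a [qpcr_plate()]
#' @return data.frame: target, sample, rq, sd, n_replicates. Control gene
#'   rows are omitted.
#' @export
relative_quantification <- function(plate) {
  stopifnot(inherits(plate, "qpcr_plate"))
  w <- plate$wells
  targets <- setdiff(unique(w$target), plate$control_gene)
  out <- list()
  for (tg in targets) {
    dct <- list()
    for (s in unique(w$sample)) {
      tw <- w[w$sample == s & w$target == tg, , drop = FALSE]
      cw <- w[w$sample == s & w$target == plate$control_gene, , drop = FALSE]
      if (nrow(tw) == 0) next
      if (nrow(cw) == 0) stop("missing control wells for sample ", s)
      ctl <- stats::setNames(cw$ct, cw$replicate)
      if (!all(as.character(tw$replicate) %in% names(ctl)))
        stop("control replicate missing for sample ", s, ", target ", tg)
      dct[[s]] <- tw$ct - unname(ctl[as.character(tw$replicate)])
    }
    if (is.null(dct[[plate$calibrator]]))
      stop("calibrator sample has no wells for target ", tg)
    cal_mean <- mean(dct[[plate$calibrator]])
    for (s in names(dct)) {
      ddct_mean <- mean(dct[[s]]) - cal_mean   # exactly 0 for the calibrator
      rq_rep <- 2^(-(dct[[s]] - cal_mean))
      out[[length(out) + 1L]] <- data.frame(
        target = tg, sample = s,
        rq = 2^(-ddct_mean),
        sd = stats::sd(rq_rep),
        n_replicates = length(rq_rep))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' RNA-seq relative expression against a theoretical calibrator
#'
#' The theoretical calibrator FPKM of a gene is the arithmetic mean of its
#' FPKM over all time points; relative expression is FPKM divided by that
#' mean, so the outputs always average to 1. This puts RNA-seq trajectories
#' on the same relative scale as qPCR RQ values for side-by-side
#' comparison.
#'
#' @param x an [expression_matrix()]
#' @param gene a gene id with positive mean FPKM
#' @return named numeric vector (one value per time point)
#' @export
rnaseq_relative_expression <- function(x, gene) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene %in% rownames(x$fpkm)) stop("unknown gene: ", gene)
  v <- x$fpkm[gene, ]
  if (mean(v) == 0) stop("gene ", gene, " has zero mean FPKM")
  v / mean(v)
}

#' Construct a cuticle thickness measurement set
#'
#' @param wings named list; each wing is a list with numeric measurement
#'   vectors `dorsal` and `ventral` (thicknesses in nm, nominally 10 equally
#'   spaced measurements per sample point)
#' @return list of class `thickness_set`
#' @export
thickness_set <- function(wings) {
  if (length(wings) == 0) stop("need at least one wing")
  for (nm in names(wings)) {
    w <- wings[[nm]]
    if (!all(c("dorsal", "ventral") %in% names(w)))
      stop("wing ", nm, " must carry both surfaces (dorsal, ventral)")
    if (any(unlist(w[c("dorsal", "ventral")]) <= 0))
      stop("thickness measurements must be positive (wing ", nm, ")")
  }
  structure(list(wings = wings), class = "thickness_set")
}

#' Per-wing dorsal/ventral cuticle thickness ratios
#'
#' Each surface's measurements are averaged, then the two means are
#' ratioed. In `thicker_over_thinner` mode (used when surface identity
#' cannot be assigned with certainty, as in wild-type wings) the larger
#' mean is the numerator, so ratios are always >= 1. In `fixed_orientation`
#' mode the ratio is dorsal over ventral as recorded (used when one surface
#' is marked, e.g. by a dorsal-driver knockdown).
#'
#' @param set a [thickness_set()]
#' @param mode `"thicker_over_thinner"` (default) or `"fixed_orientation"`
#' @return list: `ratios` (named per wing), `mean`, `sd`
#' @export
thickness_ratios <- function(set, mode = c("thicker_over_thinner",
                                           "fixed_orientation")) {
  stopifnot(inherits(set, "thickness_set"))
  mode <- match.arg(mode)
  r <- vapply(set$wings, function(w) {
    d <- mean(w$dorsal); v <- mean(w$ventral)
    if (mode == "thicker_over_thinner") max(d, v) / min(d, v) else d / v
  }, 0)
  list(ratios = r, mean = mean(r),
       sd = if (length(r) > 1) stats::sd(r) else NA_real_)
}

#' Two-sample t-test on thickness ratio lists
#'
#' @param a,b numeric ratio vectors (each length >= 2; the experimental
#'   design behind the defaults averaged >= 6 measurements per wing)
#' @param flavor `"student"` (default) or `"welch"`
#' @return list: t, df, p (two-sided), flavor
#' @export
ratio_group_test <- function(a, b, flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 ratios")
  tt <- stats::t.test(a, b, var.equal = (flavor == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, flavor = flavor)
}
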