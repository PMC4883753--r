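#' Construct an expression matrix over an ordered time grid
#'
#' The central container of the package: one non-negative FPKM value per gene
#' per time point, over a strictly increasing grid of sampling times in hours
#' after white prepupa (awp). Replicates are assumed already merged upstream
#' (one value per condition, as Cuffdiff reports them); an optional
#' replicate-level array can be attached for dispersion diagnostics only.
#'
#' @param fpkm numeric matrix, genes in rows (unique rownames required),
#'   time points in columns. All values must be finite and >= 0.
#' @param times numeric vector of time labels (hours awp), strictly
#'   increasing, one per column of `fpkm`.
#' @param replicates optional 3-d numeric array (gene x time x replicate)
#'   with the same first two dimensions as `fpkm`.
#' @return An object of class `expr_matrix` with elements `fpkm` (the
#'   validated matrix, columns named by time) and `times`.
#' @examples
#' m <- matrix(c(0, 5, 1, 1), nrow = 2, dimnames = list(c("g1", "g2"), NULL))
#' expression_matrix(m, times = c(42, 52))
#' @export
expression_matrix <- function(fpkm, times, replicates = NULL) {
  fpkm <- as.matrix(fpkm)
  if (!is.numeric(fpkm)) stop("FPKM values must be numeric")
  times <- validate_time_grid(times)
  if (ncol(fpkm) != length(times))
    stop("column count (", ncol(fpkm), ") does not match time grid length (",
         length(times), ")")
  ids <- rownames(fpkm)
  if (is.null(ids)) stop("fpkm must carry gene ids as rownames")
  if (anyDuplicated(ids))
    stop("duplicate gene id: ", ids[duplicated(ids)][1L])
  check_fpkm_values(fpkm, "FPKM")
  colnames(fpkm) <- as.character(times)
  if (!is.null(replicates)) {
    replicates <- as.array(replicates)
    if (length(dim(replicates)) != 3L ||
        !all(dim(replicates)[1:2] == dim(fpkm)))
      stop("replicates must be a gene x time x replicate array matching fpkm")
    check_fpkm_values(replicates, "replicate FPKM")
  }
  structure(list(fpkm = fpkm, times = times, replicates = replicates),
            class = "expr_matrix")
}

validate_time_grid <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("time grid needs at least 2 points")
  if (anyNA(times)) stop("time labels must be numeric")
  if (any(diff(times) <= 0)) stop("time labels must be strictly increasing")
  times
}

check_fpkm_values <- function(x, what) {
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(what, " must be finite and non-negative; offending entry at row ",
         i[[1L]], ", column ", i[[2L]])
  }
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x$fpkm), " genes x ", length(x$times),
      " time points (", paste(x$times, collapse = ", "), " hr awp)\n",
      sep = "")
  if (!is.null(x$replicates))
    cat("  with ", dim(x$replicates)[3L], " attached replicates\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$fpkm)

#' Gene ids of an expression or isoform matrix
#' @param x an `expr_matrix` or `isoform_matrix`
#' @return character vector of ids in storage order
#' @export
gene_ids <- function(x) UseMethod("gene_ids")

#' @export
gene_ids.expr_matrix <- function(x) rownames(x$fpkm)

#' @export
gene_ids.isoform_matrix <- function(x) unique(unname(x$gene))

#' Adjacent (neighboring) time-point pairs of a grid
#'
#' Adjacency follows sort order of the labels, not equal spacing.
#' @param times strictly increasing numeric time labels
#' @return two-column matrix of neighboring time labels
#' @export
neighbor_pairs <- function(times) {
  times <- validate_time_grid(times)
  cbind(t1 = times[-length(times)], t2 = times[-1L])
}

#' Construct an isoform matrix with isoform-to-gene grouping
#'
#' @param fpkm numeric matrix, isoforms in rows (unique rownames), time
#'   points in columns; finite, non-negative.
#' @param gene character vector mapping each isoform to its single parent
#'   gene, either named by isoform id or in row order.
#' @param times strictly increasing numeric time labels.
#' @return An object of class `isoform_matrix` with elements `fpkm`, `gene`
#'   (named by isoform id) and `times`.
#' @export
isoform_matrix <- function(fpkm, gene, times) {
  fpkm <- as.matrix(fpkm)
  times <- validate_time_grid(times)
  ids <- rownames(fpkm)
  if (is.null(ids)) stop("fpkm must carry isoform ids as rownames")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("isoform id listed more than once: ", dup)
  }
  if (ncol(fpkm) != length(times)) stop("column count does not match grid")
  check_fpkm_values(fpkm, "isoform FPKM")
  gene <- as.character(gene)
  if (!is.null(names(gene))) {
    if (!setequal(names(gene), ids)) stop("gene map names must match isoform ids")
    gene <- gene[ids]
  } else {
    if (length(gene) != length(ids))
      stop("gene map length does not match isoform count")
    names(gene) <- ids
  }
  colnames(fpkm) <- as.character(times)
  structure(list(fpkm = fpkm, gene = gene, times = times),
            class = "isoform_matrix")
}

#' @export
print.isoform_matrix <- function(x, ...) {
  cat("Isoform matrix: ", nrow(x$fpkm), " isoforms of ",
      length(unique(x$gene)), " genes x ", length(x$times),
      " time points\n", sep = "")
  invisible(x)
}
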