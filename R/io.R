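#' Read an FPKM table into an expression matrix
#'
#' Two tab-delimited dialects are accepted. The canonical wide dialect has a
#' `gene_id` column followed by one column per time point, headed by the
#' numeric time label (hours awp). The long dialect has columns
#' `gene_id`, `time`, `fpkm`, one row per cell. Readers never coerce:
#' negative, missing or non-numeric FPKM values are errors, not zeros.
#'
#' @param path path to a TSV file
#' @param dialect `"wide"` (default) or `"long"`
#' @return an [expression_matrix()]
#' @export
read_expression_table <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (dialect == "wide") {
    if (ncol(df) < 3L || names(df)[1L] != "gene_id")
      stop("malformed header in ", path,
           ": expected gene_id followed by time columns")
    times <- suppressWarnings(as.numeric(names(df)[-1L]))
    if (anyNA(times))
      stop("malformed header in ", path, ": non-numeric time label '",
           names(df)[-1L][which(is.na(times))[1L]], "'")
    fpkm <- parse_fpkm_block(df[-1L], path)
    rownames(fpkm) <- df[[1L]]
    if (anyDuplicated(df[[1L]]))
      stop("duplicate gene id in ", path, ": ",
           df[[1L]][duplicated(df[[1L]])][1L])
    expression_matrix(fpkm, times)
  } else {
    need <- c("gene_id", "time", "fpkm")
    if (!all(need %in% names(df)))
      stop("long dialect needs columns gene_id, time, fpkm")
    times <- sort(unique(as.numeric(df$time)))
    genes <- unique(df$gene_id)
    key <- paste(df$gene_id, df$time)
    if (anyDuplicated(key))
      stop("duplicate (gene, time) cell in ", path, ": ",
           key[duplicated(key)][1L])
    if (nrow(df) != length(genes) * length(times))
      stop("long table in ", path, " has missing cells")
    fpkm <- matrix(NA_real_, length(genes), length(times),
                   dimnames = list(genes, as.character(times)))
    fpkm[cbind(df$gene_id, as.character(as.numeric(df$time)))] <-
      parse_numeric_strict(df$fpkm, path, "fpkm")
    expression_matrix(fpkm, times)
  }
}

parse_fpkm_block <- function(df, path) {
  out <- vapply(seq_along(df),
                function(j) parse_numeric_strict(df[[j]], path, names(df)[j]),
                numeric(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- names(df)
  out
}

parse_numeric_strict <- function(x, path, col) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    i <- which(is.na(v))[1L]
    stop("non-numeric FPKM in ", path, ", column '", col, "', row ", i,
         ": '", x[i], "'")
  }
  v
}

#' Write an expression matrix as wide TSV
#' @param x an [expression_matrix()]
#' @param path output path
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$fpkm), x$fpkm,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isoform FPKM table
#'
#' Expects TSV columns `isoform_id`, `gene_id`, then one column per time
#' label. Genes with a single isoform are retained; an isoform id occurring
#' on two rows (hence possibly under two genes) is an error.
#'
#' @param path path to a TSV file
#' @return an [isoform_matrix()]
#' @export
read_isoform_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("isoform_id", "gene_id")))
    stop("malformed header in ", path,
         ": expected isoform_id, gene_id, time columns")
  times <- suppressWarnings(as.numeric(names(df)[-(1:2)]))
  if (anyNA(times)) stop("non-numeric time label in header of ", path)
  fpkm <- parse_fpkm_block(df[-(1:2)], path)
  rownames(fpkm) <- df[[1L]]
  isoform_matrix(fpkm, gene = stats::setNames(df[[2L]], df[[1L]]),
                 times = times)
}

#' Write an isoform matrix as TSV
#' @param x an [isoform_matrix()]
#' @param path output path
#' @export
write_isoform_table <- function(x, path) {
  stopifnot(inherits(x, "isoform_matrix"))
  df <- data.frame(isoform_id = rownames(x$fpkm),
                   gene_id = unname(x$gene[rownames(x$fpkm)]),
                   x$fpkm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read named gene-label lists into an annotation set
#'
#' Each file is either one gene id per line (a binary label set such as
#' cuticle_protein or tf_dna_binding) or two tab-separated columns
#' gene / category (a GO-like multimap). Duplicated ids within a label file
#' are deduplicated; an empty file yields an empty set with a warning.
#'
#' @param paths named character vector of file paths; the names become the
#'   label (or category-map) names
#' @return list of class `annotation_set` with elements `labels` (named list
#'   of character vectors) and `categories` (named list of named lists
#'   mapping category -> gene ids)
#' @export
read_annotation_lists <- function(paths = character()) {
  labels <- list()
  categories <- list()
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p)) stop("unreadable annotation file: ", p)
    lines <- readLines(p)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warning("annotation file ", p, " is empty; label '", nm,
              "' is an empty set")
      labels[[nm]] <- character()
      next
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (all(lengths(parts) >= 2L)) {
      gene <- vapply(parts, `[[`, "", 1L)
      cat_ <- vapply(parts, `[[`, "", 2L)
      categories[[nm]] <- split(gene, cat_)
      categories[[nm]] <- lapply(categories[[nm]], unique)
    } else {
      labels[[nm]] <- unique(vapply(parts, `[[`, "", 1L))
    }
  }
  structure(list(labels = labels, categories = categories),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set:", length(x$labels), "label sets,",
      length(x$categories), "category maps\n")
  for (nm in names(x$labels))
    cat("  ", nm, ": ", length(x$labels[[nm]]), " genes\n", sep = "")
  invisible(x)
}

#' Read a pairwise differential-expression table
#'
#' Columns `gene`, `t1`, `t2`, `fold`, `q` — one record per gene per tested
#' time-point pair, as exported from an upstream differential-expression run.
#' Significance filtering is downstream; all records are stored.
#'
#' @param path path to a TSV file
#' @param times optional time grid; if given, records whose pair is not drawn
#'   from the grid are dropped
#' @return data.frame of class `de_result`
#' @export
read_de_table <- function(path, times = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("gene", "t1", "t2", "fold", "q")
  if (!all(need %in% names(df)))
    stop("DE table needs columns gene, t1, t2, fold, q")
  df <- df[need]
  if (any(!is.finite(df$q) | df$q < 0 | df$q > 1))
    stop("q values must lie in [0, 1]")
  if (any(!is.na(df$fold) & df$fold <= 0))
    stop("fold changes must be positive")
  if (!is.null(times)) {
    times <- validate_time_grid(times)
    df <- df[df$t1 %in% times & df$t2 %in% times, , drop = FALSE]
  }
  class(df) <- c("de_result", "data.frame")
  df
}

#' Write a differential-expression table
#' @param de a `de_result` data.frame
#' @param path output path
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA into a protein set
#'
#' The id is the header token before the first whitespace. Sequences are
#' uppercased and line wrapping removed; an empty sequence record is an
#' error. Non-standard letters are kept (and flagged later by the
#' composition screen), never silently dropped.
#'
#' @param path path to a FASTA file
#' @return named character vector of class `protein_set` (names = ids)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids)) stop("duplicate protein id: ",
                               ids[duplicated(ids)][1L])
  if (any(!nzchar(seqs)))
    stop("empty sequence record: ", ids[!nzchar(seqs)][1L])
  names(seqs) <- ids
  structure(seqs, class = "protein_set")
}

#' Write a protein set as FASTA
#' @param proteins a `protein_set` (named character vector of sequences)
#' @param path output path
#' @export
write_protein_fasta <- function(proteins, path) {
  aas <- Biostrings::AAStringSet(unclass(proteins))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}
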