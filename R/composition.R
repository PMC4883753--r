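AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid composition of one protein
#'
#' Exact residue counts and fractions over the 20 standard amino acids.
#' Non-standard letters (X, U, B, Z, ...) are excluded from the fraction
#' denominator but reported, never silently dropped. Cuticle proteins are
#' often short and compositionally biased, so the report carries a `short`
#' flag (length below `short_len`) and a `high_single_residue` flag (some
#' residue at or above `high_frac`); a typical globular protein has no
#' residue above about 10%.
#'
#' @param sequence one amino-acid sequence (character scalar)
#' @param short_len length threshold for the short flag (default 200 aa)
#' @param high_frac fraction threshold for the high-single-residue flag
#'   (default 0.2)
#' @return list of class `composition_report`: `length` (standard residues
#'   counted), `fraction` (named, the 20 standard residues), `absent`
#'   (residues with fraction 0), `max_residue`, `max_fraction`,
#'   `nonstandard` (named counts, possibly empty), `short`,
#'   `high_single_residue`
#' @export
compose <- function(sequence, short_len = 200, high_frac = 0.2) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("need one non-empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1L]]
  counts <- table(factor(chars, levels = AA20))
  nonstd <- table(chars[!chars %in% AA20])
  len <- sum(counts)
  if (len == 0) stop("sequence has no standard residues")
  frac <- as.numeric(counts) / len
  names(frac) <- AA20
  structure(list(
    length = len,
    fraction = frac,
    absent = AA20[frac == 0],
    max_residue = AA20[which.max(frac)],
    max_fraction = max(frac),
    nonstandard = nonstd,
    short = len < short_len,
    high_single_residue = max(frac) >= high_frac), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Protein of", x$length, "aa;",
      "max residue", x$max_residue,
      sprintf("(%.1f%%);", 100 * x$max_fraction),
      length(x$absent), "absent residues\n")
  invisible(x)
}

#' Compositional screen over a protein set
#'
#' Applies [compose()] to every protein and summarizes the hallmarks of
#' candidate structural cuticle proteins: short length, residues entirely
#' absent (Trp and Cys absences are the most telling), any residue at or
#' above `high_frac` or `very_high_frac`, and exceeding the ~10% per-residue
#' cap typical of an average protein.
#'
#' @param proteins a `protein_set` (named character vector of sequences)
#' @param short_len short-protein threshold (default 200 aa)
#' @param high_frac high single-residue fraction (default 0.20)
#' @param very_high_frac very high single-residue fraction (default 0.30)
#' @param avg_cap the average-protein per-residue cap (default 0.10)
#' @return list: `table` (per-protein data.frame: id, length, short,
#'   max_residue, max_fraction, high flags, exceeds_avg_cap, n_absent,
#'   absent as comma string), `lacking` (per-residue counts of proteins
#'   lacking that residue), `summary` (named counts per flag)
#' @export
screen_candidates <- function(proteins, short_len = 200, high_frac = 0.20,
                              very_high_frac = 0.30, avg_cap = 0.10) {
  stopifnot(length(proteins) > 0,
            high_frac > 0, high_frac < 1, very_high_frac > 0,
            very_high_frac < 1, avg_cap > 0, avg_cap < 1)
  reps <- lapply(unclass(proteins), compose, short_len = short_len,
                 high_frac = high_frac)
  tab <- data.frame(
    id = names(proteins),
    length = vapply(reps, `[[`, 0, "length"),
    short = vapply(reps, `[[`, TRUE, "short"),
    max_residue = vapply(reps, `[[`, "", "max_residue"),
    max_fraction = vapply(reps, `[[`, 0, "max_fraction"),
    row.names = NULL)
  tab$any_ge_high <- tab$max_fraction >= high_frac
  tab$any_ge_very_high <- tab$max_fraction >= very_high_frac
  tab$exceeds_avg_cap <- tab$max_fraction > avg_cap
  tab$n_absent <- vapply(reps, function(r) length(r$absent), 0L)
  tab$absent <- vapply(reps, function(r) paste(r$absent, collapse = ","), "")
  lacking <- vapply(AA20, function(aa)
    sum(vapply(reps, function(r) aa %in% r$absent, TRUE)), 0L)
  list(table = tab,
       lacking = lacking,
       summary = c(n = nrow(tab),
                   n_short = sum(tab$short),
                   n_ge_high = sum(tab$any_ge_high),
                   n_ge_very_high = sum(tab$any_ge_very_high),
                   n_exceeds_avg_cap = sum(tab$exceeds_avg_cap)))
}
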