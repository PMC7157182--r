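# Degenerate reverse translation and mapping-score verification.
#
# Each amino acid is represented by a single degenerate codon: at every codon
# position, the IUPAC letter whose base set is the union of that position's
# bases over all codons of the amino acid (standard genetic code). The
# representation is deliberately permissive -- e.g. serine becomes "WSN",
# which also admits some non-serine codons -- because the score it feeds is a
# verification diagnostic layered on top of exact coordinate arithmetic, not
# a search tool.

# IUPAC letter keyed by its sorted base set, e.g. "CT" -> "Y".
.iupac_by_set <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  keys <- vapply(strsplit(m, ""), function(b) paste(sort(b), collapse = ""),
                 character(1))
  stats::setNames(names(m), keys)
})

# Base set (character vector) for each IUPAC letter.
.iupac_sets <- local({
  strsplit(Biostrings::IUPAC_CODE_MAP, "")
})

# One degenerate codon per amino acid, precomputed from the standard code.
.degenerate_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  aas <- setdiff(unique(gc), "*")
  m <- Biostrings::IUPAC_CODE_MAP
  keys <- vapply(strsplit(m, ""), function(b) paste(sort(b), collapse = ""),
                 character(1))
  by_set <- stats::setNames(names(m), keys)
  out <- vapply(aas, function(aa) {
    codons <- strsplit(names(gc)[gc == aa], "")
    paste(vapply(1:3, function(i) {
      bases <- sort(unique(vapply(codons, `[`, character(1), i)))
      by_set[[paste(bases, collapse = "")]]
    }, character(1)), collapse = "")
  }, character(1))
  stats::setNames(out, aas)
})

#' Reverse-translate an amino-acid sequence into an IUPAC degenerate string
#'
#' Each residue contributes exactly one degenerate codon under the standard
#' genetic code: the IUPAC letter at each of the three positions covers the
#' union of bases seen at that position across all of the residue's codons.
#' Glycine, for example, is coded by GGT, GGC, GGA and GGG and reverse
#' translates to `"GGN"`.
#'
#' `X` (unknown residue) maps to `"NNN"`; `U` (selenocysteine) also maps to
#' `"NNN"`, with a warning, since its UGA codon is context-recoded and cannot
#' be represented in the standard code.
#'
#' @param aa_sequence Amino-acid string in one-letter code (no stop `*`).
#' @return An object of class `degenerate_seq`: a list with `symbols`
#'   (the degenerate nucleotide string, length `3 * nchar(aa_sequence)`)
#'   and `source_aa_length`.
#' @examples
#' aa_to_iupac("G")$symbols  # "GGN"
#' aa_to_iupac("MW")$symbols # "ATGTGG"
#' @export
aa_to_iupac <- function(aa_sequence) {
  stopifnot(is.character(aa_sequence), length(aa_sequence) == 1L)
  aa <- strsplit(toupper(aa_sequence), "")[[1]]
  if (length(aa) == 0L) {
    return(structure(list(symbols = "", source_aa_length = 0L),
                     class = "degenerate_seq"))
  }
  bad <- which(!(aa %in% c(names(.degenerate_codons), "X", "U")))
  if (length(bad) > 0L) {
    stop("unsupported amino-acid letter '", aa[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  if (any(aa == "U")) {
    warning("selenocysteine (U) reverse-translated as NNN", call. = FALSE)
  }
  codons <- ifelse(aa %in% c("X", "U"), "NNN", .degenerate_codons[aa])
  structure(list(symbols = paste(codons, collapse = ""),
                 source_aa_length = length(aa)),
            class = "degenerate_seq")
}

#' @export
print.degenerate_seq <- function(x, ...) {
  cat("<degenerate_seq> ", x$source_aa_length, " aa, ",
      nchar(x$symbols), " nt: ", x$symbols, "\n", sep = "")
  invisible(x)
}

#' Compatibility of a degenerate base with a concrete base
#'
#' `TRUE` iff the concrete base belongs to the degenerate letter's IUPAC base
#' set. An `N` in the concrete (cDNA) position is treated as incompatible
#' unless the degenerate letter is itself `N`: unknown bases must not inflate
#' verification scores.
#'
#' @param degenerate_base Single IUPAC nucleotide letter.
#' @param concrete_base Single base, one of A/C/G/T/N.
#' @return Logical scalar (vectorised over equal-length inputs).
#' @export
iupac_compatible <- function(degenerate_base, concrete_base) {
  d <- toupper(degenerate_base)
  b <- toupper(concrete_base)
  if (length(d) != length(b)) stop("inputs must have equal length")
  ok_d <- d %in% names(.iupac_sets)
  ok_b <- b %in% c("A", "C", "G", "T", "N")
  if (!all(ok_d)) stop("invalid IUPAC letter: ", d[!ok_d][1])
  if (!all(ok_b)) stop("invalid concrete base: ", b[!ok_b][1])
  mapply(function(di, bi) {
    if (bi == "N") return(di == "N")
    bi %in% .iupac_sets[[di]]
  }, d, b, USE.NAMES = FALSE)
}

#' Mapping score: fraction of compatible positions
#'
#' The verification half of the double-check: a domain is first placed on its
#' cDNA by coordinate arithmetic, then its degenerate reverse translation is
#' compared position by position against the concrete cDNA subsequence. The
#' score is the ratio of compatible positions to all positions, in `[0, 1]`;
#' 1.0 means every base of the cDNA interval is admitted by the degenerate
#' codons.
#'
#' @param degenerate A `degenerate_seq` (or plain IUPAC string).
#' @param concrete Concrete nucleotide string of the same length.
#' @return Numeric scalar in `[0, 1]` (exact ratio, not rounded; exports
#'   round to two decimals).
#' @examples
#' mapping_score(aa_to_iupac("G"), "GGC") # 1
#' mapping_score("GGN", "GAC")            # 2/3
#' @export
mapping_score <- function(degenerate, concrete) {
  sym <- if (inherits(degenerate, "degenerate_seq")) degenerate$symbols
         else degenerate
  stopifnot(is.character(sym), is.character(concrete))
  if (nchar(sym) == 0L) stop("empty degenerate sequence")
  if (nchar(sym) != nchar(concrete)) {
    stop("length mismatch: degenerate ", nchar(sym),
         " nt vs concrete ", nchar(concrete), " nt")
  }
  d <- strsplit(toupper(sym), "")[[1]]
  b <- strsplit(toupper(concrete), "")[[1]]
  sum(iupac_compatible(d, b)) / length(d)
}
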