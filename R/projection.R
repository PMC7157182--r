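# Projection of cDNA intervals onto genomic coordinates.
#
# Conventions: cDNA positions are 1-based inclusive (GenBank); genomic
# intervals are 0-based half-open internally (genePred). On the plus strand
# cDNA base 1 is the first base of the leftmost exon; on the minus strand it
# is the last base of the rightmost exon, so cDNA ascends as the genome
# descends. Exon indices are reported in transcription order (5'->3').

#' Construct a gene model
#'
#' @param transcript_id Transcript accession (e.g. NM_*).
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   intervals, ascending, non-overlapping.
#' @return A `gene_model` object.
#' @export
gene_model <- function(transcript_id, chrom, strand, exon_starts, exon_ends) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L)
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_starts >= exon_ends)) {
    stop("gene model ", transcript_id, ": exon with start >= end")
  }
  if (is.unsorted(exon_starts, strictly = TRUE)) {
    stop("gene model ", transcript_id, ": exons not sorted ascending")
  }
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1] < exon_ends[-length(exon_ends)])) {
    stop("gene model ", transcript_id, ": overlapping exons")
  }
  structure(list(transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exon_starts = exon_starts,
                 exon_ends = exon_ends),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$transcript_id, " ", x$chrom, "(", x$strand, ") ",
      length(x$exon_starts), " exon(s), ", transcript_length(x), " nt\n",
      sep = "")
  invisible(x)
}

#' Total exonic (transcript) length of a gene model
#' @param model A `gene_model`.
#' @return Integer.
#' @export
transcript_length <- function(model) {
  sum(model$exon_ends - model$exon_starts)
}

#' Per-base map from cDNA position to genomic position
#'
#' Brute-force bijection between `[1, transcript length]` and the exonic
#' bases of the model; the independent oracle against which the interval
#' projection is checked. Returns a function of a 1-based cDNA position
#' giving the 0-based genomic position.
#'
#' @param model A `gene_model`.
#' @return `function(pos)`; errors on out-of-range positions.
#' @export
per_base_map <- function(model) {
  # genomic positions of transcript bases, in transcription order
  g <- unlist(mapply(seq, model$exon_starts, model$exon_ends - 1L,
                     SIMPLIFY = FALSE))
  if (model$strand == "-") g <- rev(g)
  n <- length(g)
  function(pos) {
    pos <- as.integer(pos)
    if (any(pos < 1L | pos > n)) {
      stop("cDNA position out of range [1, ", n, "]")
    }
    g[pos]
  }
}

#' Project a cDNA interval onto genomic segments
#'
#' Splits the interval across exons: the output is the ordered list of
#' maximal runs within single exons, in transcription order, with 0-based
#' half-open genomic coordinates. The sum of segment lengths always equals
#' the interval length. Domains spanning an exon junction therefore yield
#' one row per exon touched.
#'
#' @param cdna_start,cdna_end 1-based inclusive cDNA interval.
#' @param model A `gene_model`.
#' @return `data.frame` with columns `chrom`, `g_start`, `g_end` (0-based
#'   half-open), `exon_index` (transcription order, 1-based).
#' @export
cdna_to_genomic <- function(cdna_start, cdna_end, model) {
  cdna_start <- as.integer(cdna_start)
  cdna_end <- as.integer(cdna_end)
  tl <- transcript_length(model)
  if (cdna_start < 1L || cdna_end < cdna_start) {
    stop("invalid cDNA interval ", cdna_start, "..", cdna_end)
  }
  if (cdna_end > tl) {
    stop("cDNA interval ", cdna_start, "..", cdna_end,
         " exceeds transcript length ", tl,
         " (gene model / cDNA mismatch for ", model$transcript_id, ")")
  }
  lens <- model$exon_ends - model$exon_starts
  n_ex <- length(lens)
  # exons in transcription order
  ord <- if (model$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  cum_end <- cumsum(lens[ord])          # cDNA coordinate of each exon's last base
  cum_start <- cum_end - lens[ord] + 1L # cDNA coordinate of each exon's first base
  out <- vector("list", n_ex)
  for (k in seq_len(n_ex)) {
    lo <- max(cdna_start, cum_start[k])
    hi <- min(cdna_end, cum_end[k])
    if (lo > hi) next
    e <- ord[k]
    # offsets of lo/hi within the exon, 1-based from transcription start
    o1 <- lo - cum_start[k] + 1L
    o2 <- hi - cum_start[k] + 1L
    if (model$strand == "+") {
      gs <- model$exon_starts[e] + o1 - 1L
      ge <- model$exon_starts[e] + o2
    } else {
      gs <- model$exon_ends[e] - o2
      ge <- model$exon_ends[e] - o1 + 1L
    }
    out[[k]] <- data.frame(chrom = model$chrom, g_start = gs, g_end = ge,
                           exon_index = k, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}
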