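# Batch variant annotation against a domain store.
#
# Each query position is matched against the record intervals; for every
# hit the covered protein residue is back-calculated through the record's
# own transcript frame:
#   residue = (cdna_pos - cds_start) %/% 3 + 1
# where cdna_pos is recovered from the genomic position via the segment's
# stored cDNA offset (strand-aware). A variant hitting two isoforms can
# legitimately report two residue numbers.

#' Parse variant queries from text
#'
#' One query per line, `chrom:pos` or `chrom<TAB>pos`; an optional third
#' field (or anything after the position) becomes the label. Malformed
#' lines are skipped and reported. More than 100 well-formed queries are
#' accepted with a notice (batch web tools commonly cap at 100; the library
#' does not).
#'
#' @param text Path or literal text.
#' @return `data.frame` with columns `chrom`, `pos`, `label`; attribute
#'   `errors` lists skipped line numbers with messages.
#' @export
parse_queries <- function(text) {
  lines <- .read_lines(text)
  keep <- nzchar(trimws(lines))
  out <- list()
  errs <- character(0)
  lineno <- 0L
  for (ln in lines) {
    lineno <- lineno + 1L
    if (!nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "[:\t]")[[1]]
    if (length(f) >= 2L && grepl("^[0-9]+$", f[2])) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = f[1], pos = as.integer(f[2]),
        label = if (length(f) >= 3L) paste(f[-(1:2)], collapse = " ")
                else paste0(f[1], ":", f[2]),
        stringsAsFactors = FALSE)
    } else {
      errs <- c(errs, sprintf("line %d: cannot parse '%s'", lineno,
                              trimws(ln)))
    }
  }
  q <- if (length(out) > 0) do.call(rbind, out)
       else data.frame(chrom = character(0), pos = integer(0),
                       label = character(0), stringsAsFactors = FALSE)
  if (nrow(q) > 100L) {
    message("note: ", nrow(q), " queries (web batch tools often cap at 100)")
  }
  attr(q, "errors") <- errs
  q
}

#' Read variant queries from a VCF
#'
#' Uses only CHROM, POS and ID; a minimal position-based reader (alleles
#' and genotypes are irrelevant to positional domain annotation). The input
#' must carry a `#CHROM` header line.
#'
#' @param vcf Path or literal VCF text.
#' @return `data.frame` with `chrom`, `pos`, `label` (the VCF ID field, or
#'   `chrom:pos` when ID is ".").
#' @export
read_vcf_queries <- function(vcf) {
  lines <- .read_lines(vcf)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0L) stop("not a VCF: missing #CHROM header line")
  body <- lines[seq_along(lines) > hdr[1]]
  body <- body[nzchar(trimws(body)) & !startsWith(body, "#")]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, character(1), 1L),
    pos = as.integer(vapply(f, `[`, character(1), 2L)),
    label = vapply(f, function(x) {
      id <- if (length(x) >= 3L) x[3] else "."
      if (is.na(id) || id == ".") paste0(x[1], ":", x[2]) else id
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Annotate variant positions against a domain store
#'
#' Per query: all matching domain records plus the protein residue covered
#' by the position (per matched record's own transcript frame). Queries
#' hitting no domain are kept with an explicit no-domain marker so the
#' output has at least one row per query.
#'
#' @param queries `data.frame` from [parse_queries()] /
#'   [read_vcf_queries()], or any frame with `chrom`, `pos` and optional
#'   `label`.
#' @param store A `domain_store` built by [build_store()] (imported stores
#'   lack transcript frames; residues are then `NA`).
#' @return `data.frame` with columns `query`, `chrom`, `pos`, `hit`
#'   (logical), `gene_symbol`, `protein_id`, `transcript_id`, `kind`,
#'   `name`, `residue`, `score`, `start`, `end`, `note`.
#' @export
annotate_variants <- function(queries, store) {
  if (is.null(queries$label)) {
    queries$label <- paste0(queries$chrom, ":", queries$pos)
  }
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    chrom <- queries$chrom[i]
    pos <- queries$pos[i]
    lab <- queries$label[i]
    hits <- withCallingHandlers(
      query_position(store, chrom, pos),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(hits) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        query = lab, chrom = chrom, pos = pos, hit = FALSE,
        gene_symbol = NA_character_, protein_id = NA_character_,
        transcript_id = NA_character_, kind = NA_character_,
        name = "no domain", residue = NA_integer_, score = NA_real_,
        start = NA_integer_, end = NA_integer_, note = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    res <- vapply(seq_len(nrow(hits)), function(k) {
      .residue_at(store, hits$row[k], pos)
    }, integer(1))
    rows[[length(rows) + 1L]] <- data.frame(
      query = lab, chrom = chrom, pos = pos, hit = TRUE,
      gene_symbol = hits$gene_symbol, protein_id = hits$protein_id,
      transcript_id = hits$transcript_id, kind = hits$kind,
      name = hits$name, residue = res, score = hits$score,
      start = hits$start, end = hits$end, note = hits$note,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(query = character(0), chrom = character(0),
                         pos = integer(0), hit = logical(0),
                         gene_symbol = character(0),
                         protein_id = character(0),
                         transcript_id = character(0), kind = character(0),
                         name = character(0), residue = integer(0),
                         score = numeric(0), start = integer(0),
                         end = integer(0), note = character(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Protein residue covered by 1-based genomic pos within store row `row`.
.residue_at <- function(store, row, pos) {
  fr <- store$frames[row, ]
  if (is.na(fr$seg_cdna_start) || is.na(fr$cds_start)) return(NA_integer_)
  rec <- store$records[row, ]
  cdna_pos <- if (rec$strand == "+") {
    fr$seg_cdna_start + (pos - rec$start)
  } else {
    fr$seg_cdna_start + (rec$end - pos)
  }
  as.integer((cdna_pos - fr$cds_start) %/% 3L + 1L)
}

#' Expand a genomic range into per-base queries
#'
#' Convenience for range inputs: expands `start..end` to one query per
#' base; downstream annotation output can be deduplicated on record
#' identity by the caller.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive range.
#' @param label Optional shared label.
#' @return Query `data.frame` as for [parse_queries()].
#' @export
expand_range_query <- function(chrom, start, end, label = NULL) {
  stopifnot(end >= start)
  pos <- seq.int(start, end)
  data.frame(chrom = chrom, pos = pos,
             label = if (is.null(label)) paste0(chrom, ":", start, "-", end)
                     else label,
             stringsAsFactors = FALSE)
}
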