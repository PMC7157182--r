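# Ingest of protein flat files, cDNA FASTA and genePred exon tables.
#
# Coordinate conventions at the boundary follow each format: amino-acid and
# cDNA coordinates are 1-based inclusive (GenBank), genomic exon intervals
# 0-based half-open (genePred). No flat-file parser for GenPept feature
# tables ships with the installed sequence packages, so the (small) subset
# of the format consumed here -- LOCUS/VERSION framing, Region/Site/CDS
# features with their qualifiers, and the ORIGIN residue block -- is parsed
# directly.

# Accept either a file path (optionally .gz) or literal multi-line text.
.read_lines <- function(x) {
  if (length(x) > 1L) return(x)
  if (grepl("\n", x, fixed = TRUE)) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  if (file.exists(x)) {
    con <- if (grepl("\\.gz$", x)) gzfile(x, "rt") else file(x, "rt")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  # single line of literal text (possibly empty)
  x
}

#' Parse a CDS `coded_by` qualifier
#'
#' The qualifier names the mRNA accession and the 1-based cDNA span of the
#' coding sequence; its start is the frame offset ("shift") that anchors all
#' protein-to-cDNA arithmetic. Partial-CDS markers (`<`, `>`) are stripped
#' and flagged. `join(...)`/`complement(...)` forms are refused rather than
#' guessed.
#'
#' @param qualifier Location string, e.g. `"NM_000546.5:203..1384"`.
#' @return List with `transcript_id`, `cds_start`, `cds_end`,
#'   `partial_5p`, `partial_3p`.
#' @export
parse_coded_by <- function(qualifier) {
  q <- trimws(gsub("\"", "", qualifier))
  if (grepl("^(complement|join)\\(", q)) {
    stop("unsupported coded_by location form: ", q, call. = FALSE)
  }
  m <- regmatches(q, regexec(
    "^([A-Za-z_0-9]+(?:\\.[0-9]+)?):(<?)([0-9]+)\\.\\.(>?)([0-9]+)$", q))[[1]]
  if (length(m) == 0L) stop("cannot parse coded_by qualifier: ", q,
                            call. = FALSE)
  list(transcript_id = m[2],
       cds_start = as.integer(m[4]),
       cds_end = as.integer(m[6]),
       partial_5p = m[3] == "<",
       partial_3p = m[5] == ">")
}

# Expand a feature location string into aa intervals.
# Supports: "a", "a..b", "<a..>b", and order(...) whose elements are
# expanded per residue (sites are residue-level entities; an enclosing span
# would fabricate unannotated residues).
.parse_feature_location <- function(loc) {
  loc <- trimws(loc)
  one <- function(tok) {
    tok <- gsub("[<>]", "", tok)
    if (grepl("^[0-9]+\\.\\.[0-9]+$", tok)) {
      p <- as.integer(strsplit(tok, "..", fixed = TRUE)[[1]])
      return(data.frame(aa_start = p[1], aa_end = p[2]))
    }
    if (grepl("^[0-9]+$", tok)) {
      p <- as.integer(tok)
      return(data.frame(aa_start = p, aa_end = p))
    }
    NULL
  }
  if (grepl("^order\\(.*\\)$", loc)) {
    toks <- strsplit(sub("^order\\((.*)\\)$", "\\1", loc), ",")[[1]]
    parts <- lapply(trimws(toks), one)
    if (any(vapply(parts, is.null, logical(1)))) return(NULL)
    # expand every listed position to a single-residue interval
    pos <- unlist(lapply(parts, function(p) seq(p$aa_start, p$aa_end)))
    return(data.frame(aa_start = pos, aa_end = pos))
  }
  one(loc)
}

# Split a feature block into (location, qualifiers); qualifiers may continue
# over multiple lines.
.parse_qualifiers <- function(lines) {
  txt <- character(0)
  cur <- NULL
  for (ln in lines) {
    s <- trimws(ln)
    if (startsWith(s, "/")) {
      if (!is.null(cur)) txt <- c(txt, cur)
      cur <- s
    } else if (!is.null(cur)) {
      cur <- paste(cur, s)
    }
  }
  if (!is.null(cur)) txt <- c(txt, cur)
  out <- list()
  for (q in txt) {
    m <- regmatches(q, regexec("^/([A-Za-z_]+)=?\"?(.*?)\"?$", q))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

#' Parse a GenPept-style protein flat file
#'
#' Extracts, per record: the protein accession (VERSION, falling back to
#' LOCUS), the amino-acid sequence from the ORIGIN block, the gene symbol
#' and `coded_by` CDS span from the CDS feature, and every `Region` and
#' `Site` feature with its name (`region_name` / `site_type`), note and
#' amino-acid interval. Compound `order(...)` site locations are expanded
#' into one single-residue feature per listed position. Records without a
#' `coded_by` qualifier are skipped with a warning; features with
#' unparseable locations are skipped and counted.
#'
#' @param flatfile Path to a `.gp` file (optionally gzipped) or literal text.
#' @return List of `protein_record` objects, with attribute `report`:
#'   a list with `records_in`, `records_ok`, `records_skipped`,
#'   `features_skipped`.
#' @export
parse_genpept <- function(flatfile) {
  lines <- .read_lines(flatfile)
  recs <- list()
  rec_lines <- list()
  cur <- character(0)
  in_rec <- FALSE
  for (ln in lines) {
    if (grepl("^LOCUS", ln)) {
      if (in_rec) stop("malformed record boundary: LOCUS before // near record ",
                       length(rec_lines) + 1L)
      in_rec <- TRUE
      cur <- ln
    } else if (grepl("^//\\s*$", ln)) {
      if (!in_rec) stop("malformed record boundary: // without LOCUS near record ",
                        length(rec_lines) + 1L)
      rec_lines[[length(rec_lines) + 1L]] <- c(cur, ln)
      cur <- character(0)
      in_rec <- FALSE
    } else if (in_rec) {
      cur <- c(cur, ln)
    }
  }
  if (in_rec) stop("malformed record boundary: unterminated record ",
                   length(rec_lines) + 1L)

  n_skip <- 0L
  n_feat_skip <- 0L
  for (rl in rec_lines) {
    rec <- .parse_one_genpept(rl)
    n_feat_skip <- n_feat_skip + rec$features_skipped
    if (is.null(rec$record)) {
      n_skip <- n_skip + 1L
      warning("record ", rec$id, " skipped: ", rec$why, call. = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- rec$record
    }
  }
  attr(recs, "report") <- list(records_in = length(rec_lines),
                               records_ok = length(recs),
                               records_skipped = n_skip,
                               features_skipped = n_feat_skip)
  recs
}

.parse_one_genpept <- function(lines) {
  locus_id <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[1])
  ver <- grep("^VERSION", lines, value = TRUE)
  protein_id <- if (length(ver) > 0) sub("^VERSION\\s+(\\S+).*$", "\\1", ver[1])
                else locus_id

  # ORIGIN block: residue lines "   1 mdep qsdl ..."
  o <- grep("^ORIGIN", lines)
  aa <- ""
  if (length(o) == 1L && o < length(lines)) {
    seq_lines <- lines[(o + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    aa <- toupper(gsub("[^A-Za-z*]", "", paste(seq_lines, collapse = "")))
  }

  # FEATURES table: feature keys start at column 6, qualifiers at column 22
  f0 <- grep("^FEATURES", lines)
  feats <- list()
  gene_symbol <- NA_character_
  coded_by <- NULL
  n_feat_skip <- 0L
  if (length(f0) == 1L) {
    fend <- if (length(o) == 1L) o - 1L else length(lines)
    flines <- lines[(f0 + 1L):fend]
    is_key <- grepl("^\\s{2,7}\\S", flines) & !grepl("^\\s{8,}", flines)
    starts <- which(is_key)
    bounds <- c(starts, length(flines) + 1L)
    for (i in seq_along(starts)) {
      block <- flines[starts[i]:(bounds[i + 1L] - 1L)]
      key <- sub("^\\s*(\\S+).*$", "\\1", block[1])
      loc <- sub("^\\s*\\S+\\s*(.*)$", "\\1", block[1])
      # location may continue before the first qualifier
      j <- 2L
      while (j <= length(block) && !grepl("^\\s*/", block[j]) &&
             nzchar(trimws(block[j]))) {
        loc <- paste0(loc, trimws(block[j]))
        j <- j + 1L
      }
      quals <- .parse_qualifiers(if (j <= length(block))
                                   block[j:length(block)] else character(0))
      if (key == "CDS") {
        if (!is.null(quals$gene)) gene_symbol <- quals$gene
        if (!is.null(quals$coded_by)) coded_by <- quals$coded_by
      } else if (key %in% c("Region", "Site")) {
        iv <- .parse_feature_location(loc)
        if (is.null(iv)) {
          n_feat_skip <- n_feat_skip + 1L
          next
        }
        kind <- tolower(key)
        nm <- if (kind == "region") quals$region_name else quals$site_type
        for (r in seq_len(nrow(iv))) {
          feats[[length(feats) + 1L]] <- domain_feature(
            kind = kind,
            name = if (is.null(nm)) NA_character_ else nm,
            note = if (is.null(quals$note)) NA_character_ else quals$note,
            aa_start = iv$aa_start[r], aa_end = iv$aa_end[r],
            location_raw = loc)
        }
      }
    }
  }

  if (is.null(coded_by)) {
    return(list(record = NULL, id = protein_id, why = "no coded_by qualifier",
                features_skipped = n_feat_skip))
  }
  cb <- tryCatch(parse_coded_by(coded_by), error = function(e) e)
  if (inherits(cb, "error")) {
    return(list(record = NULL, id = protein_id,
                why = conditionMessage(cb), features_skipped = n_feat_skip))
  }
  rec <- tryCatch(
    protein_record(protein_id = protein_id, gene_symbol = gene_symbol,
                   transcript_id = cb$transcript_id,
                   aa_sequence = aa, cds_start = cb$cds_start,
                   cds_end = cb$cds_end, features = feats,
                   partial_5p = cb$partial_5p, partial_3p = cb$partial_3p),
    error = function(e) e)
  if (inherits(rec, "error")) {
    return(list(record = NULL, id = protein_id,
                why = conditionMessage(rec), features_skipped = n_feat_skip))
  }
  list(record = rec, id = protein_id, why = NULL,
       features_skipped = n_feat_skip)
}

#' Construct a domain feature (site or region)
#'
#' @param kind `"site"` or `"region"`.
#' @param name Domain name (from `region_name`/`site_type`).
#' @param note Free-text note.
#' @param aa_start,aa_end 1-based inclusive amino-acid interval.
#' @param location_raw Original location string.
#' @return A `domain_feature` object.
#' @export
domain_feature <- function(kind, name, note, aa_start, aa_end,
                           location_raw = NA_character_) {
  stopifnot(kind %in% c("site", "region"))
  aa_start <- as.integer(aa_start)
  aa_end <- as.integer(aa_end)
  if (aa_start < 1L || aa_end < aa_start) {
    stop("invalid amino-acid interval ", aa_start, "..", aa_end)
  }
  structure(list(kind = kind, name = name, note = note,
                 aa_start = aa_start, aa_end = aa_end,
                 location_raw = location_raw),
            class = "domain_feature")
}

#' Construct a protein record
#'
#' @param protein_id Protein accession (NP_*, version retained).
#' @param gene_symbol Gene symbol.
#' @param transcript_id mRNA accession (NM_*).
#' @param aa_sequence One-letter amino-acid string (no stop).
#' @param cds_start,cds_end 1-based inclusive CDS span in the cDNA.
#' @param features List of `domain_feature`.
#' @param cdna_sequence Optional cDNA string (attach later with
#'   [attach_cdna()]).
#' @param partial_5p,partial_3p Partial-CDS flags from `coded_by`.
#' @return A `protein_record` object with a `cds_stop_included` flag:
#'   `TRUE` when the CDS span equals `3*nchar(aa) + 3` (stop codon in CDS),
#'   `FALSE` when it equals `3*nchar(aa)`, `NA` otherwise (partial CDS).
#' @export
protein_record <- function(protein_id, gene_symbol, transcript_id,
                           aa_sequence, cds_start, cds_end,
                           features = list(), cdna_sequence = NA_character_,
                           partial_5p = FALSE, partial_3p = FALSE) {
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (cds_start < 1L || cds_end < cds_start) {
    stop("invalid CDS span ", cds_start, "..", cds_end)
  }
  aa_len <- nchar(aa_sequence)
  span <- cds_end - cds_start + 1L
  stop_inc <- if (span == 3L * aa_len + 3L) TRUE
              else if (span == 3L * aa_len) FALSE
              else NA
  for (f in features) {
    if (f$aa_end > aa_len) {
      stop("feature ", f$name, " interval ", f$aa_start, "..", f$aa_end,
           " exceeds protein length ", aa_len, " in ", protein_id)
    }
  }
  structure(list(protein_id = protein_id, gene_symbol = gene_symbol,
                 transcript_id = transcript_id, aa_sequence = aa_sequence,
                 cdna_sequence = cdna_sequence, cds_start = cds_start,
                 cds_end = cds_end, cds_stop_included = stop_inc,
                 partial_5p = partial_5p, partial_3p = partial_3p,
                 features = features, valid = TRUE,
                 invalid_reason = NA_character_),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$protein_id, " (", x$transcript_id, ", gene ",
      x$gene_symbol, "): ", nchar(x$aa_sequence), " aa, CDS ", x$cds_start,
      "..", x$cds_end, ", ", length(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

#' Read transcript gene models from a genePred table
#'
#' Accepts either the minimal 8-column layout (name, chrom, strand, txStart,
#' txEnd, exonCount, exonStarts, exonEnds) or the standard 10-column
#' genePred layout with cdsStart/cdsEnd between txEnd and exonCount; extra
#' trailing columns are ignored. Exon intervals are 0-based half-open.
#' Rows whose exon lists disagree with exonCount, or whose exons overlap,
#' are rejected with a warning; duplicated transcript ids keep the last row
#' (logged).
#'
#' @param genepred Path to a tab-separated file (optionally gzipped) or
#'   literal text.
#' @return Named list of `gene_model`, keyed by transcript id.
#' @export
read_gene_models <- function(genepred) {
  lines <- .read_lines(genepred)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  models <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      warning("genePred row with ", length(f), " columns rejected",
              call. = FALSE)
      next
    }
    # standard genePred has numeric cdsStart/cdsEnd at 6..7 and exonCount at 8
    std <- length(f) >= 10L && grepl("^[0-9]+$", f[6]) &&
           grepl("^[0-9]+$", f[7]) && grepl("^[0-9]+$", f[8])
    ec_i <- if (std) 8L else 6L
    id <- f[1]; chrom <- f[2]; strand <- f[3]
    n_exon <- suppressWarnings(as.integer(f[ec_i]))
    starts <- suppressWarnings(as.integer(strsplit(f[ec_i + 1L], ",")[[1]]))
    ends <- suppressWarnings(as.integer(strsplit(f[ec_i + 2L], ",")[[1]]))
    if (is.na(n_exon) || length(starts) != n_exon || length(ends) != n_exon ||
        anyNA(starts) || anyNA(ends)) {
      warning("genePred row for ", id, " rejected: exonCount mismatch",
              call. = FALSE)
      next
    }
    gm <- tryCatch(gene_model(id, chrom, strand, starts, ends),
                   error = function(e) e)
    if (inherits(gm, "error")) {
      warning("genePred row for ", id, " rejected: ", conditionMessage(gm),
              call. = FALSE)
      next
    }
    if (!is.null(models[[id]])) {
      warning("duplicate transcript ", id, ": keeping last row",
              call. = FALSE)
    }
    models[[id]] <- gm
  }
  models
}

# Strip a trailing ".N" version from an accession.
.strip_version <- function(x) sub("\\.[0-9]+$", "", x)

#' Attach cDNA sequences from a FASTA file to protein records
#'
#' Matches each record's transcript accession against the FASTA headers,
#' first exactly, then with versions stripped (logged). After attachment the
#' CDS span is re-checked against the cDNA length; records whose CDS exceeds
#' the cDNA are flagged invalid and excluded from mapping.
#'
#' @param records List of `protein_record` from [parse_genpept()].
#' @param fasta Path to a FASTA file (optionally gzipped) or literal text.
#' @return The list with `cdna_sequence` filled in where a match exists;
#'   attribute `report` counts attached / unmatched / invalid records.
#' @export
attach_cdna <- function(records, fasta) {
  lines <- .read_lines(fasta)
  seqs <- list()
  hdr <- NULL
  buf <- character(0)
  flush <- function() {
    if (!is.null(hdr)) {
      seqs[[hdr]] <<- toupper(paste(buf, collapse = ""))
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      hdr <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      buf <- character(0)
    } else {
      buf <- c(buf, gsub("\\s", "", ln))
    }
  }
  flush()
  unversioned <- stats::setNames(names(seqs), .strip_version(names(seqs)))

  n_att <- 0L; n_un <- 0L; n_inv <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    key <- rec$transcript_id
    hit <- if (!is.null(seqs[[key]])) key
           else {
             uk <- unversioned[.strip_version(key)]
             if (!is.na(uk)) {
               message("transcript ", key, " matched FASTA entry ", uk,
                       " (version-insensitive)")
               unname(uk)
             } else NA_character_
           }
    if (is.na(hit)) {
      n_un <- n_un + 1L
      next
    }
    rec$cdna_sequence <- seqs[[hit]]
    if (rec$cds_end > nchar(rec$cdna_sequence)) {
      rec$valid <- FALSE
      rec$invalid_reason <- sprintf("CDS end %d exceeds cDNA length %d",
                                    rec$cds_end, nchar(rec$cdna_sequence))
      n_inv <- n_inv + 1L
    } else {
      n_att <- n_att + 1L
    }
    records[[i]] <- rec
  }
  attr(records, "report") <- list(attached = n_att, unmatched = n_un,
                                  invalid = n_inv)
  records
}
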