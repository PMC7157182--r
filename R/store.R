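# The domain-record table: one row per (feature x exon segment), with
# interval queries and CSV/JSON/SQL export. The backing container is an
# in-memory table indexed for overlap queries with GenomicRanges; the three
# flat exports are derived views of the same single-table shape.

.record_columns <- c("gene_symbol", "protein_id", "transcript_id", "strand",
                     "kind", "name", "score", "chrom", "start", "end",
                     "note", "exon_index")

# "chr1" and "1" refer to the same chromosome internally.
.norm_chrom <- function(x) sub("^chr", "", x)

.empty_records <- function() {
  data.frame(gene_symbol = character(0), protein_id = character(0),
             transcript_id = character(0), strand = character(0),
             kind = character(0), name = character(0), score = numeric(0),
             chrom = character(0), start = integer(0), end = integer(0),
             note = character(0), exon_index = integer(0),
             stringsAsFactors = FALSE)
}

.new_store <- function(records, frames = NULL, report = NULL) {
  rownames(records) <- NULL
  if (is.null(frames)) {
    frames <- data.frame(seg_cdna_start = rep(NA_integer_, nrow(records)),
                         cds_start = rep(NA_integer_, nrow(records)))
  }
  structure(list(records = records, frames = frames, report = report),
            class = "domain_store")
}

#' Build a domain store from protein records and gene models
#'
#' For every feature of every valid, cDNA-attached record whose transcript
#' has a gene model, computes the cDNA interval ([domain_to_cdna()]),
#' projects it onto the genome ([cdna_to_genomic()]), and emits one row per
#' genomic segment. A feature that fails mapping or projection is excluded
#' whole (never partially emitted) and counted. Exported coordinates are
#' 1-based inclusive; the mapping score is rounded to two decimals.
#'
#' @param records List of `protein_record` (after [attach_cdna()]).
#' @param models Named list of `gene_model` keyed by transcript id (from
#'   [read_gene_models()]); version-stripped fallback matching is applied.
#' @return A `domain_store`. Its `report` tallies `features_in`,
#'   `features_mapped`, `features_failed`, `records_without_model`, and
#'   `records_emitted` (table rows).
#' @export
build_store <- function(records, models) {
  unversioned <- if (length(models) > 0) {
    stats::setNames(names(models), .strip_version(names(models)))
  } else character(0)
  rows <- list()
  frames <- list()
  features_in <- 0L
  features_failed <- 0L
  no_model <- 0L
  for (rec in records) {
    features_in <- features_in + length(rec$features)
    if (!isTRUE(rec$valid) || is.na(rec$cdna_sequence)) {
      features_failed <- features_failed + length(rec$features)
      next
    }
    model <- models[[rec$transcript_id]]
    if (is.null(model)) {
      uk <- unversioned[.strip_version(rec$transcript_id)]
      if (!is.na(uk)) model <- models[[unname(uk)]]
    }
    if (is.null(model)) {
      no_model <- no_model + 1L
      features_failed <- features_failed + length(rec$features)
      next
    }
    for (f in rec$features) {
      seg <- tryCatch({
        iv <- domain_to_cdna(f, rec)
        s <- cdna_to_genomic(iv$cdna_start, iv$cdna_end, model)
        s$score <- iv$score
        s$cdna_start <- iv$cdna_start
        s
      }, error = function(e) e)
      if (inherits(seg, "error")) {
        features_failed <- features_failed + 1L
        next
      }
      # cDNA coordinate of each segment's first (transcription-order) base
      seg_lens <- seg$g_end - seg$g_start
      seg_cdna_start <- seg$cdna_start[1] + c(0L, cumsum(seg_lens))[seq_len(nrow(seg))]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = rec$gene_symbol, protein_id = rec$protein_id,
        transcript_id = rec$transcript_id, strand = model$strand,
        kind = f$kind, name = f$name, score = round(seg$score, 2),
        chrom = seg$chrom, start = seg$g_start + 1L, end = seg$g_end,
        note = f$note, exon_index = seg$exon_index,
        stringsAsFactors = FALSE)
      frames[[length(frames) + 1L]] <- data.frame(
        seg_cdna_start = as.integer(seg_cdna_start),
        cds_start = rep(rec$cds_start, nrow(seg)))
    }
  }
  records_df <- if (length(rows) > 0) do.call(rbind, rows) else .empty_records()
  frames_df <- if (length(frames) > 0) do.call(rbind, frames)
               else data.frame(seg_cdna_start = integer(0),
                               cds_start = integer(0))
  report <- list(features_in = features_in,
                 features_mapped = features_in - features_failed,
                 features_failed = features_failed,
                 records_without_model = no_model,
                 records_emitted = nrow(records_df))
  .new_store(records_df, frames_df, report)
}

#' @export
print.domain_store <- function(x, ...) {
  cat("<domain_store> ", nrow(x$records), " record(s) on ",
      length(unique(x$records$chrom)), " chromosome(s)\n", sep = "")
  if (!is.null(x$report)) {
    cat("  features mapped: ", x$report$features_mapped, "/",
        x$report$features_in, "\n", sep = "")
  }
  invisible(x)
}

#' Number of rows in a domain store
#' @param store A `domain_store`.
#' @return Integer row count.
#' @export
store_size <- function(store) nrow(store$records)

# GRanges interval index over the record table (normalized chrom names).
.store_granges <- function(store) {
  r <- store$records
  GenomicRanges::GRanges(
    seqnames = .norm_chrom(r$chrom),
    ranges = IRanges::IRanges(start = r$start, end = r$end))
}

#' Query a domain store by genomic position
#'
#' Returns every record whose 1-based inclusive interval covers the
#' position. Chromosome names are normalized ("chr1" and "1" match). An
#' unknown chromosome yields an empty result with a warning, not an error.
#'
#' @param store A `domain_store`.
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position.
#' @return `data.frame` of matching records, ordered by
#'   (chrom, start, protein_id, name); a `row` column gives the store row.
#' @export
query_position <- function(store, chrom, pos) {
  r <- store$records
  if (nrow(r) == 0L) return(cbind(r, row = integer(0)))
  qc <- .norm_chrom(chrom)
  if (!(qc %in% .norm_chrom(r$chrom))) {
    warning("chromosome ", chrom, " not present in store", call. = FALSE)
    return(cbind(r[0, , drop = FALSE], row = integer(0)))
  }
  q <- GenomicRanges::GRanges(qc, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, .store_granges(store))
  idx <- S4Vectors::subjectHits(hits)
  out <- r[idx, , drop = FALSE]
  out$row <- idx
  out <- out[order(out$chrom, out$start, out$protein_id, out$name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a domain store
#'
#' Three flat formats over the same field list, in the fixed column order:
#' CSV (header + one row per record), JSON (array of objects with identical
#' field names) and SQL (a `CREATE TABLE` plus one `INSERT` per record,
#' executable by any standard SQL engine). All three round-trip through
#' [read_store()] to an identical record set.
#'
#' @param store A `domain_store`.
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"sql"`.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path, format = c("csv", "json", "sql")) {
  format <- match.arg(format)
  r <- store$records[, .record_columns, drop = FALSE]
  switch(format,
    csv = utils::write.csv(r, path, row.names = FALSE, na = ""),
    json = jsonlite::write_json(r, path, dataframe = "rows", na = "null",
                                auto_unbox = TRUE, digits = NA),
    sql = {
      esc <- function(x) {
        ifelse(is.na(x), "NULL",
               paste0("'", gsub("'", "''", as.character(x)), "'"))
      }
      num <- function(x) ifelse(is.na(x), "NULL", format(x, scientific = FALSE))
      ddl <- paste0(
        "CREATE TABLE domain_records (\n",
        "  gene_symbol TEXT, protein_id TEXT, transcript_id TEXT,\n",
        "  strand TEXT, kind TEXT, name TEXT, score REAL, chrom TEXT,\n",
        "  \"start\" INTEGER, \"end\" INTEGER, note TEXT, exon_index INTEGER\n",
        ");")
      ins <- if (nrow(r) == 0) character(0) else paste0(
        "INSERT INTO domain_records VALUES (",
        esc(r$gene_symbol), ", ", esc(r$protein_id), ", ",
        esc(r$transcript_id), ", ", esc(r$strand), ", ", esc(r$kind), ", ",
        esc(r$name), ", ", num(r$score), ", ", esc(r$chrom), ", ",
        num(r$start), ", ", num(r$end), ", ", esc(r$note), ", ",
        num(r$exon_index), ");")
      writeLines(c(ddl, ins), path)
    })
  invisible(path)
}

#' Re-import an exported domain store
#'
#' Reads any of the three [write_store()] formats back into a
#' `domain_store`. The SQL reader parses the dump's `INSERT` statements
#' directly. Imported stores carry the full record table but not the
#' per-segment transcript frames, so [annotate_variants()] on an imported
#' store reports `NA` residues.
#'
#' @param path File written by [write_store()].
#' @param format `"csv"`, `"json"` or `"sql"`.
#' @return A `domain_store`.
#' @export
read_store <- function(path, format = c("csv", "json", "sql")) {
  format <- match.arg(format)
  r <- switch(format,
    csv = {
      d <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(score = "numeric"),
                           na.strings = "")
      d
    },
    json = {
      d <- jsonlite::fromJSON(path)
      if (length(d) == 0L) .empty_records() else as.data.frame(d)
    },
    sql = .read_sql_dump(path))
  if (nrow(r) > 0) {
    r$start <- as.integer(r$start)
    r$end <- as.integer(r$end)
    r$exon_index <- as.integer(r$exon_index)
    r$score <- as.numeric(r$score)
    for (col in c("gene_symbol", "protein_id", "transcript_id", "strand",
                  "kind", "name", "chrom", "note")) {
      r[[col]] <- as.character(r[[col]])
    }
  } else {
    r <- .empty_records()
  }
  .new_store(r[, .record_columns, drop = FALSE])
}

# Parse the INSERT statements of a write_store(..., format = "sql") dump.
.read_sql_dump <- function(path) {
  lines <- .read_lines(path)
  ins <- grep("^INSERT INTO domain_records VALUES", lines, value = TRUE)
  if (length(ins) == 0L) return(.empty_records())
  parse_row <- function(ln) {
    body <- sub("^INSERT INTO domain_records VALUES \\((.*)\\);$", "\\1", ln)
    vals <- character(0)
    i <- 1L
    n <- nchar(body)
    while (i <= n) {
      ch <- substr(body, i, i)
      if (ch == "'") {
        j <- i + 1L
        buf <- ""
        while (j <= n) {
          cj <- substr(body, j, j)
          if (cj == "'") {
            if (substr(body, j + 1L, j + 1L) == "'") {
              buf <- paste0(buf, "'"); j <- j + 2L
            } else break
          } else {
            buf <- paste0(buf, cj); j <- j + 1L
          }
        }
        vals <- c(vals, buf)
        i <- j + 1L
        while (i <= n && substr(body, i, i) %in% c(",", " ")) i <- i + 1L
      } else {
        j <- regexpr(",", substr(body, i, n), fixed = TRUE)
        tok <- if (j == -1) substr(body, i, n)
               else substr(body, i, i + j - 2L)
        vals <- c(vals, trimws(tok))
        i <- if (j == -1) n + 1L else i + j
        while (i <= n && substr(body, i, i) == " ") i <- i + 1L
      }
    }
    vals[vals == "NULL"] <- NA_character_
    vals
  }
  m <- t(vapply(ins, parse_row, character(length(.record_columns))))
  r <- as.data.frame(m, stringsAsFactors = FALSE)
  names(r) <- .record_columns
  rownames(r) <- NULL
  r
}
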