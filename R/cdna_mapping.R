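# Placement of domain features on cDNA and score verification.
#
# Residue i of a protein occupies cDNA positions
#   (i-1)*3 + cds_start ... i*3 + cds_start - 1
# (1-based inclusive), so residue 1 begins exactly at the CDS start. The
# placement is verified by comparing the feature's degenerate reverse
# translation against the concrete cDNA subsequence (double-verification);
# the resulting mapping score is stored, never used as a filter.

#' Map a domain feature to its cDNA interval
#'
#' Converts the feature's amino-acid interval into a cDNA interval via the
#' CDS offset, reverse-translates the feature's subsequence into a
#' degenerate string, and scores it against the actual cDNA subsequence.
#'
#' @param feature A `domain_feature`.
#' @param record A `protein_record` with `cdna_sequence` attached.
#' @return List of class `cdna_interval`: `cdna_start`, `cdna_end` (1-based
#'   inclusive), `degenerate` (a `degenerate_seq`), `score`.
#' @export
domain_to_cdna <- function(feature, record) {
  if (is.na(record$cdna_sequence)) {
    stop("record ", record$protein_id, " has no cDNA sequence attached")
  }
  if (feature$aa_end > nchar(record$aa_sequence)) {
    stop("feature exceeds protein length in ", record$protein_id)
  }
  cdna_start <- (feature$aa_start - 1L) * 3L + record$cds_start
  cdna_end <- feature$aa_end * 3L + record$cds_start - 1L
  if (cdna_end > record$cds_end) {
    stop("feature ", feature$name, " (", feature$aa_start, "..",
         feature$aa_end, ") maps beyond CDS end in ", record$protein_id)
  }
  sub_aa <- substr(record$aa_sequence, feature$aa_start, feature$aa_end)
  deg <- aa_to_iupac(sub_aa)
  sub_nt <- substr(record$cdna_sequence, cdna_start, cdna_end)
  score <- mapping_score(deg, sub_nt)
  structure(list(cdna_start = cdna_start, cdna_end = cdna_end,
                 degenerate = deg, score = score),
            class = "cdna_interval")
}

#' Map and verify every feature of every record
#'
#' Runs [domain_to_cdna()] over all features of all valid, cDNA-attached
#' records and aggregates the score distribution. All features are retained
#' with their scores; no score threshold is applied.
#'
#' @param records List of `protein_record` (after [attach_cdna()]).
#' @return List of class `mapping_report`: `table` (one row per feature:
#'   protein_id, transcript_id, kind, name, aa_start, aa_end, cdna_start,
#'   cdna_end, score, flag), and counts `n_features`, `n_perfect`
#'   (score == 1), `n_imperfect`, `n_errors`.
#' @export
verify_all <- function(records) {
  rows <- list()
  for (rec in records) {
    usable <- isTRUE(rec$valid) && !is.na(rec$cdna_sequence)
    for (f in rec$features) {
      if (!usable) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = rec$protein_id, transcript_id = rec$transcript_id,
          kind = f$kind, name = f$name, aa_start = f$aa_start,
          aa_end = f$aa_end, cdna_start = NA_integer_,
          cdna_end = NA_integer_, score = NA_real_,
          flag = if (isTRUE(rec$valid)) "no_cdna" else "invalid_record",
          stringsAsFactors = FALSE)
        next
      }
      iv <- tryCatch(domain_to_cdna(f, rec), error = function(e) e)
      if (inherits(iv, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = rec$protein_id, transcript_id = rec$transcript_id,
          kind = f$kind, name = f$name, aa_start = f$aa_start,
          aa_end = f$aa_end, cdna_start = NA_integer_,
          cdna_end = NA_integer_, score = NA_real_, flag = "mapping_error",
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = rec$protein_id, transcript_id = rec$transcript_id,
          kind = f$kind, name = f$name, aa_start = f$aa_start,
          aa_end = f$aa_end, cdna_start = iv$cdna_start,
          cdna_end = iv$cdna_end, score = iv$score, flag = "ok",
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(protein_id = character(0),
                         transcript_id = character(0), kind = character(0),
                         name = character(0), aa_start = integer(0),
                         aa_end = integer(0), cdna_start = integer(0),
                         cdna_end = integer(0), score = numeric(0),
                         flag = character(0), stringsAsFactors = FALSE)
  ok <- tab$flag == "ok"
  structure(list(table = tab,
                 n_features = nrow(tab),
                 n_perfect = sum(ok & tab$score == 1),
                 n_imperfect = sum(ok & tab$score < 1),
                 n_errors = sum(!ok)),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("<mapping_report> ", x$n_features, " feature(s): ", x$n_perfect,
      " score 1.0, ", x$n_imperfect, " < 1.0, ", x$n_errors, " error(s)\n",
      sep = "")
  invisible(x)
}

#' Write a mapping report table as TSV
#' @param report A `mapping_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
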