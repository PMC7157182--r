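# Synthetic fixture generator: matched (genePred, cDNA FASTA, protein flat
# file, ground truth) quadruples with known answers at every stage, so the
# whole pipeline is testable without any external downloads.
#
# The ground truth is computed through the per-base map oracle (explicit
# base-by-base projection, grouped by exon), independently of the interval
# arithmetic in cdna_to_genomic. cDNA coding sequence is built by sampling
# a true codon per residue, so every uncorrupted feature scores exactly 1.0
# by construction. Random streams are split per component (model, protein,
# corruption) from one master seed, so adding fixture kinds never perturbs
# existing expected outputs.

# Run expr under a seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# Deterministic per-component sub-seed, kept under 2^31.
.sub_seed <- function(seed, component) {
  ((as.double(seed) %% 1e7) * 131 + component * 7919) %% 2147483647
}

# concrete codons per amino acid, standard code
.codons_of <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

.region_names <- c("Pkinase", "Zinc_finger", "WD40", "LRR", "Ion_trans",
                   "PH_domain", "SH3", "Homeobox", "EGF_like", "Ank_repeat")
.site_names <- c("phosphorylation", "active", "glycosylation", "metal-binding",
                 "nitrosylation", "transmembrane", "acetylation")

#' Generate a random gene model
#'
#' Exon lengths are drawn from 30-600 bp and intron gaps from 50-5000 bp,
#' the ranges typical of compact human transcripts. Deterministic for a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param n_exons Number of exons (>= 1).
#' @param strand "+" or "-".
#' @param chrom Chromosome name.
#' @param transcript_id Accession to assign.
#' @return A `gene_model`.
#' @export
generate_gene_model <- function(seed, n_exons, strand = "+", chrom = "chr1",
                                transcript_id = "NM_FIX0001.1") {
  if (n_exons < 1L) stop("n_exons must be >= 1")
  .with_seed(.sub_seed(seed, 1L), {
    lens <- sample(30:600, n_exons, replace = TRUE)
    gaps <- if (n_exons > 1L) sample(50:5000, n_exons - 1L, replace = TRUE)
            else integer(0)
    start0 <- sample(1000:100000, 1L)
    starts <- start0 + cumsum(c(0L, lens[-n_exons] + gaps))
    gene_model(transcript_id, chrom, strand, starts, starts + lens)
  })
}

# genePred line (standard 10-column layout) for a model + CDS genomic span
.genepred_line <- function(model, cds_cdna_start, cds_cdna_end) {
  pbm <- per_base_map(model)
  g <- pbm(seq.int(cds_cdna_start, cds_cdna_end))
  paste(model$transcript_id, model$chrom, model$strand,
        min(model$exon_starts), max(model$exon_ends),
        min(g), max(g) + 1L,
        length(model$exon_starts),
        paste0(paste(model$exon_starts, collapse = ","), ","),
        paste0(paste(model$exon_ends, collapse = ","), ","),
        sep = "\t")
}

# GenPept ORIGIN block: 60 residues per line in 10-residue groups.
.origin_block <- function(aa) {
  aa <- tolower(aa)
  n <- nchar(aa)
  lines <- character(0)
  for (i in seq(1, n, by = 60)) {
    chunk <- substr(aa, i, min(i + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", i, paste(groups, collapse = " ")))
  }
  lines
}

# Feature ground truth via the per-base oracle: map every cDNA base of the
# interval, group by exon in transcription order.
.oracle_segments <- function(model, cdna_start, cdna_end) {
  pbm <- per_base_map(model)
  g <- pbm(seq.int(cdna_start, cdna_end))
  lens <- model$exon_ends - model$exon_starts
  ord <- if (model$strand == "+") seq_along(lens) else rev(seq_along(lens))
  cum_end <- cumsum(lens[ord])
  exon_of <- findInterval(seq.int(cdna_start, cdna_end) - 1L, c(0L, cum_end))
  segs <- lapply(split(g, exon_of), function(gg) {
    c(g_start = min(gg), g_end = max(gg) + 1L)
  })
  idx <- sort(unique(exon_of))
  data.frame(chrom = model$chrom,
             g_start = vapply(segs, `[[`, integer(1), "g_start")[as.character(idx)],
             g_end = vapply(segs, `[[`, integer(1), "g_end")[as.character(idx)],
             exon_index = idx, stringsAsFactors = FALSE)
}

#' Generate a synthetic protein with domains on a gene model
#'
#' Builds a random protein whose CDS (with stop codon) plus UTRs exactly
#' fills the model's transcript; the cDNA coding region is assembled by
#' sampling one true codon per residue, so every feature's mapping score is
#' 1.0 by construction. Regions are 20-200 aa (annotated protein regions
#' typically exceed 100 aa; short fixtures cap at the protein length),
#' sites 1-3 aa. When the model has more than one exon and the CDS crosses
#' a junction, at least one region is forced to span an exon junction.
#'
#' @param seed Integer seed.
#' @param model A `gene_model`.
#' @param n_regions,n_sites Feature counts.
#' @param utr5 5' UTR length in nt (default: random 0-90; the remainder of
#'   the transcript after the CDS is 3' UTR).
#' @param protein_id,gene_symbol Identifiers to assign.
#' @return List of class `fixture`: `genpept_text`, `fasta_text`,
#'   `genepred_text`, `truth` (one row per expected exon segment with
#'   0-based `g_start`/`g_end` and 1-based `start`/`end`), `aa_sequence`,
#'   `cdna_sequence`, `cds_start`, `cds_end`, `model`, ids.
#' @export
generate_protein <- function(seed, model, n_regions = 2L, n_sites = 3L,
                             utr5 = NULL, protein_id = "NP_FIX0001.1",
                             gene_symbol = "FIXG1") {
  tl <- transcript_length(model)
  .with_seed(.sub_seed(seed, 2L), {
    if (is.null(utr5)) utr5 <- sample(0:90, 1L)
    aa_len <- (tl - utr5 - 3L - sample(0:60, 1L)) %/% 3L
    if (aa_len < 25L) {
      stop("infeasible packing: transcript of ", tl,
           " nt cannot hold a >=25 aa CDS with the requested UTRs; ",
           "use a larger gene model")
    }
    aa_letters <- setdiff(names(.codons_of), "*")
    aa <- c("M", sample(aa_letters, aa_len - 1L, replace = TRUE))
    codons <- vapply(aa, function(x) sample(.codons_of[[x]], 1L), character(1))
    cds_start <- utr5 + 1L
    cds_end <- utr5 + 3L * aa_len + 3L
    utr3 <- tl - cds_end
    cdna <- paste0(
      paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE), collapse = ""),
      paste(codons, collapse = ""),
      sample(c("TAA", "TAG", "TGA"), 1L),
      paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE), collapse = ""))
    aa_seq <- paste(aa, collapse = "")

    feats <- list()
    # force one junction-spanning region where the CDS crosses a junction
    lens <- model$exon_ends - model$exon_starts
    ord <- if (model$strand == "+") seq_along(lens) else rev(seq_along(lens))
    junctions <- cumsum(lens[ord])
    junctions <- junctions[junctions >= cds_start &
                           junctions < cds_start + 3L * aa_len - 1L]
    n_forced <- 0L
    if (length(junctions) > 0L && n_regions > 0L) {
      j <- junctions[sample.int(length(junctions), 1L)]
      r1 <- (j - cds_start) %/% 3L + 1L
      a <- max(1L, r1 - sample(5:60, 1L))
      b <- min(aa_len, r1 + sample(5:60, 1L) + 1L)
      feats[[length(feats) + 1L]] <- domain_feature(
        "region", sample(.region_names, 1L), "fixture region (junction)",
        a, b)
      n_forced <- 1L
    }
    for (i in seq_len(max(0L, n_regions - n_forced))) {
      len <- min(aa_len, sample(20:200, 1L))
      a <- sample(seq_len(aa_len - len + 1L), 1L)
      feats[[length(feats) + 1L]] <- domain_feature(
        "region", sample(.region_names, 1L), "fixture region", a, a + len - 1L)
    }
    for (i in seq_len(n_sites)) {
      len <- sample(1:3, 1L)
      a <- sample(seq_len(aa_len - len + 1L), 1L)
      feats[[length(feats) + 1L]] <- domain_feature(
        "site", sample(.site_names, 1L), "fixture site", a, a + len - 1L)
    }

    # ground truth via the per-base oracle
    truth <- do.call(rbind, lapply(seq_along(feats), function(i) {
      f <- feats[[i]]
      cs <- (f$aa_start - 1L) * 3L + cds_start
      ce <- f$aa_end * 3L + cds_start - 1L
      seg <- .oracle_segments(model, cs, ce)
      data.frame(feature_id = paste0(protein_id, ":", f$kind, ":", i),
                 protein_id = protein_id,
                 transcript_id = model$transcript_id,
                 gene_symbol = gene_symbol, strand = model$strand,
                 kind = f$kind, name = f$name,
                 aa_start = f$aa_start, aa_end = f$aa_end,
                 cdna_start = cs, cdna_end = ce,
                 chrom = seg$chrom, g_start = seg$g_start,
                 g_end = seg$g_end, start = seg$g_start + 1L,
                 end = seg$g_end, exon_index = seg$exon_index,
                 score = 1.0, stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL

    # flat-file text
    feat_lines <- unlist(lapply(feats, function(f) {
      loc <- if (f$aa_start == f$aa_end) as.character(f$aa_start)
             else paste0(f$aa_start, "..", f$aa_end)
      key <- if (f$kind == "region") "Region" else "Site"
      qual <- if (f$kind == "region") "region_name" else "site_type"
      c(sprintf("     %-16s%s", key, loc),
        sprintf("                     /%s=\"%s\"", qual, f$name),
        sprintf("                     /note=\"%s\"", f$note))
    }))
    genpept_text <- paste(c(
      sprintf("LOCUS       %s %d aa            linear   PRI 01-JAN-2020",
              protein_id, aa_len),
      sprintf("DEFINITION  synthetic fixture protein %s.", gene_symbol),
      sprintf("VERSION     %s", protein_id),
      sprintf("DBSOURCE    REFSEQ: accession %s", model$transcript_id),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", aa_len),
      "                     /organism=\"synthetic fixture\"",
      feat_lines,
      sprintf("     CDS             1..%d", aa_len),
      sprintf("                     /gene=\"%s\"", gene_symbol),
      sprintf("                     /coded_by=\"%s:%d..%d\"",
              model$transcript_id, cds_start, cds_end),
      "ORIGIN",
      .origin_block(aa_seq),
      "//"), collapse = "\n")

    fasta_lines <- c(paste0(">", model$transcript_id, " synthetic fixture cDNA"),
                     substring(cdna, seq(1, nchar(cdna), 70),
                               pmin(seq(70, nchar(cdna) + 69, 70), nchar(cdna))))
    structure(list(genpept_text = genpept_text,
                   fasta_text = paste(fasta_lines, collapse = "\n"),
                   genepred_text = .genepred_line(model, cds_start, cds_end),
                   truth = truth, aa_sequence = aa_seq, cdna_sequence = cdna,
                   cds_start = cds_start, cds_end = cds_end, model = model,
                   protein_id = protein_id,
                   transcript_id = model$transcript_id,
                   gene_symbol = gene_symbol),
              class = "fixture")
  })
}

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture> ", x$protein_id, " on ", x$transcript_id, " (",
      x$model$chrom, x$model$strand, "), ", nchar(x$aa_sequence), " aa, ",
      nrow(x$truth), " truth segment(s)\n", sep = "")
  invisible(x)
}

#' Generate a complete random fixture
#'
#' Convenience wrapper: draws exon count, strand and feature counts, then
#' builds the gene model and protein. Sub-seeds are split per component
#' from the master seed.
#'
#' @param seed Integer master seed.
#' @param n_exons Exon count (default random 1-8).
#' @param strand Strand (default random).
#' @param index Serial number used to make accessions unique within a set.
#' @return A `fixture`.
#' @export
generate_fixture <- function(seed, n_exons = NULL, strand = NULL,
                             index = 1L) {
  pars <- .with_seed(.sub_seed(seed, 3L), {
    list(n_exons = if (is.null(n_exons)) sample(1:8, 1L) else n_exons,
         strand = if (is.null(strand)) sample(c("+", "-"), 1L) else strand,
         chrom = sample(paste0("chr", c(1:22, "X")), 1L),
         n_regions = sample(1:3, 1L), n_sites = sample(1:4, 1L))
  })
  nm <- sprintf("NM_FIX%04d.1", index)
  np <- sprintf("NP_FIX%04d.1", index)
  gene <- sprintf("FIXG%d", index)
  # small models cannot always hold a CDS; regrow until packing fits
  for (try in 0:20) {
    model <- generate_gene_model(seed + try * 1000L, pars$n_exons,
                                 pars$strand, pars$chrom, transcript_id = nm)
    fx <- tryCatch(
      generate_protein(seed + try * 1000L, model, pars$n_regions,
                       pars$n_sites, protein_id = np, gene_symbol = gene),
      error = function(e) e)
    if (!inherits(fx, "error")) return(fx)
  }
  stop("could not pack a CDS into any generated model for seed ", seed)
}

#' Plant verifiable mismatches in a fixture's cDNA
#'
#' Mutates chosen cDNA positions to a base outside the degenerate letter's
#' base set at that position, guaranteeing each hit scores as a mismatch.
#' Positions whose degenerate letter is `N` (fourfold-degenerate codon
#' positions) admit no mismatching base and are rejected. Expected
#' per-feature scores `(L - hits) / L` are emitted alongside.
#'
#' @param fixture A `fixture`.
#' @param n Number of corruption positions to draw inside feature intervals
#'   (ignored when `positions` given).
#' @param positions Optional explicit 1-based cDNA positions.
#' @param seed Integer seed for position/base draws.
#' @return List: `fasta_text` (mutated), `cdna_sequence`, `positions`,
#'   `rejected` (positions refused because the degenerate letter is N),
#'   `expected` (data.frame feature_id, length_nt, hits, expected_score).
#' @export
corrupt_cdna <- function(fixture, n = 1L, positions = NULL, seed = 1L) {
  rec_aa <- strsplit(fixture$aa_sequence, "")[[1]]
  cds_start <- fixture$cds_start
  deg_at <- function(p) {
    r <- (p - cds_start) %/% 3L + 1L
    cp <- (p - cds_start) %% 3L + 1L
    if (r < 1L || r > length(rec_aa)) return(NA_character_)
    substr(.degenerate_codons[[rec_aa[r]]], cp, cp)
  }
  truth1 <- unique(fixture$truth[, c("feature_id", "cdna_start", "cdna_end")])
  .with_seed(.sub_seed(seed, 4L), {
    if (is.null(positions)) {
      cand <- unique(unlist(mapply(seq, truth1$cdna_start, truth1$cdna_end,
                                   SIMPLIFY = FALSE)))
      cand <- cand[vapply(cand, function(p) {
        d <- deg_at(p); !is.na(d) && d != "N"
      }, logical(1))]
      if (length(cand) < n) stop("not enough corruptible positions")
      positions <- sort(cand[sample.int(length(cand), n)])
    }
    rejected <- integer(0)
    cdna <- strsplit(fixture$cdna_sequence, "")[[1]]
    kept <- integer(0)
    for (p in positions) {
      d <- deg_at(p)
      if (is.na(d) || d == "N") {
        rejected <- c(rejected, p)
        next
      }
      bad <- setdiff(c("A", "C", "G", "T"), .iupac_sets[[d]])
      cdna[p] <- if (length(bad) == 1L) bad else sample(bad, 1L)
      kept <- c(kept, p)
    }
    expected <- do.call(rbind, lapply(seq_len(nrow(truth1)), function(i) {
      L <- truth1$cdna_end[i] - truth1$cdna_start[i] + 1L
      hits <- sum(kept >= truth1$cdna_start[i] & kept <= truth1$cdna_end[i])
      data.frame(feature_id = truth1$feature_id[i], length_nt = L,
                 hits = hits, expected_score = (L - hits) / L,
                 stringsAsFactors = FALSE)
    }))
    seq_str <- paste(cdna, collapse = "")
    fasta_lines <- c(paste0(">", fixture$transcript_id,
                            " synthetic fixture cDNA (corrupted)"),
                     substring(seq_str, seq(1, nchar(seq_str), 70),
                               pmin(seq(70, nchar(seq_str) + 69, 70),
                                    nchar(seq_str))))
    list(fasta_text = paste(fasta_lines, collapse = "\n"),
         cdna_sequence = seq_str, positions = kept, rejected = rejected,
         expected = expected)
  })
}

#' Write a set of fixtures to disk
#'
#' Emits the four matched files consumed by the pipeline: `genes.genePred`,
#' `cdna.fa`, `proteins.gp` and `truth.csv`.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of genes.
#' @param max_exons Upper bound on exon count per gene.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of `fixture` objects.
#' @export
simulate_fixture_set <- function(seed, n_genes, max_exons = 8L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- lapply(seq_len(n_genes), function(i) {
    n_ex <- .with_seed(.sub_seed(seed + i, 5L), sample(seq_len(max_exons), 1L))
    generate_fixture(seed + i, n_exons = n_ex, index = i)
  })
  writeLines(vapply(fixtures, `[[`, character(1), "genepred_text"),
             file.path(out_dir, "genes.genePred"))
  writeLines(vapply(fixtures, `[[`, character(1), "fasta_text"),
             file.path(out_dir, "cdna.fa"))
  writeLines(vapply(fixtures, `[[`, character(1), "genpept_text"),
             file.path(out_dir, "proteins.gp"))
  truth <- do.call(rbind, lapply(fixtures, `[[`, "truth"))
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(fixtures)
}
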