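# Independent oracles used across the suite.

# Brute-force degenerate codon for one amino acid: enumerate its codons,
# take the positionwise base union, and look the set up in the IUPAC table.
# Kept deliberately separate from the package's precomputed table.
oracle_degenerate_codon <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codons <- strsplit(names(gc)[gc == aa], "")
  set_to_letter <- function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    sets <- vapply(strsplit(Biostrings::IUPAC_CODE_MAP, ""),
                   function(b) paste(sort(b), collapse = ""), character(1))
    names(Biostrings::IUPAC_CODE_MAP)[match(key, sets)]
  }
  paste(vapply(1:3, function(i) {
    set_to_letter(vapply(codons, `[`, character(1), i))
  }, character(1)), collapse = "")
}

# All concrete codons of an amino acid.
oracle_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

# Per-base projection of a cDNA interval, merged into runs that stay within
# one exon: the independent route against cdna_to_genomic's interval
# arithmetic. Runs are split where consecutive genomic positions are not
# adjacent in transcription direction.
oracle_project <- function(model, cdna_start, cdna_end) {
  pbm <- per_base_map(model)
  g <- pbm(seq.int(cdna_start, cdna_end))
  step <- if (model$strand == "+") 1L else -1L
  breaks <- which(diff(g) != step)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(g))
  data.frame(chrom = model$chrom,
             g_start = pmin(g[starts], g[ends]),
             g_end = pmax(g[starts], g[ends]) + 1L,
             stringsAsFactors = FALSE)
}

# A tiny deterministic hand-made two-exon model used by several tests.
toy_model <- function(strand = "+") {
  gene_model("NM_TOY.1", "chr1", strand, c(100L, 300L), c(200L, 400L))
}

# Build a store from one fixture.
fixture_store <- function(fx) {
  build_store_from_files(fx$genpept_text, fx$fasta_text, fx$genepred_text)
}
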