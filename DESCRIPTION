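Package: domainmapr
Title: Projection of Annotated Protein Domains onto Genomic Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps protein domain annotations (sites and regions from
    GenPept-style feature tables) onto genomic coordinates. Domains are
    placed on their cDNA by coding-sequence offset arithmetic and verified
    by comparing an IUPAC degenerate reverse translation against the
    concrete cDNA sequence (a per-domain mapping score); cDNA intervals are
    then split across exons of a genePred transcript model into exact
    genomic segments. The resulting table supports positional variant
    annotation with protein residue back-calculation, CSV/JSON/SQL export,
    and two-by-two chi-square / odds-ratio enrichment analysis of domain
    annotation between variant groups. A seeded synthetic fixture generator
    emits matched gene models, cDNA FASTA and protein flat files with exact
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
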