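# a tiny hand-built record: 3 residues MGW, CDS at offset 4 (3 nt 5' UTR),
# stop codon included
tiny_record <- function(cdna = NULL) {
  if (is.null(cdna)) cdna <- paste0("AAA", "ATG", "GGA", "TGG", "TAA", "CC")
  protein_record("NP_T.1", "TST", "NM_T.1", "MGW",
                 cds_start = 4L, cds_end = 15L, cdna_sequence = cdna,
                 features = list())
}

test_that("residue i occupies cDNA positions (i-1)*3+shift .. i*3+shift-1", {
  rec <- tiny_record()
  f1 <- domain_feature("site", "s", "n", 1, 1)
  iv <- domain_to_cdna(f1, rec)
  expect_identical(iv$cdna_start, 4L)
  expect_identical(iv$cdna_end, 6L)
  expect_identical(iv$score, 1)

  f23 <- domain_feature("region", "r", "n", 2, 3)
  iv2 <- domain_to_cdna(f23, rec)
  expect_identical(iv2$cdna_start, 7L)
  expect_identical(iv2$cdna_end, 12L)
  expect_identical(nchar(iv2$degenerate$symbols), 6L)
  expect_identical(iv2$score, 1)

  # the first-residue rule with a large published-style shift
  rec2 <- protein_record("NP_U.1", "U", "NM_U.1", "M", 203L, 208L,
                         cdna_sequence = paste0(
                           paste(rep("A", 202), collapse = ""), "ATGTAA"))
  iv3 <- domain_to_cdna(domain_feature("site", "s", "n", 1, 1), rec2)
  expect_identical(iv3$cdna_start, 203L)
  expect_identical(iv3$cdna_end, 205L)
})

test_that("glycine-only features verify as GGN against GGx codons", {
  rec <- protein_record("NP_G.1", "G", "NM_G.1", "GGG", 1L, 9L,
                        cdna_sequence = "GGAGGCGGT")
  iv <- domain_to_cdna(domain_feature("region", "g", "n", 1, 3), rec)
  expect_identical(iv$degenerate$symbols, "GGNGGNGGN")
  expect_identical(iv$score, 1)
})

test_that("features beyond the CDS or without cDNA raise mapping errors", {
  rec <- tiny_record()
  rec$cds_end <- 12L  # stop codon absent: residue 3 ends exactly at 12
  expect_silent(domain_to_cdna(domain_feature("site", "s", "n", 3, 3), rec))
  rec$cds_end <- 11L
  expect_error(domain_to_cdna(domain_feature("site", "s", "n", 3, 3), rec),
               "beyond CDS end")
  rec2 <- tiny_record()
  rec2$cdna_sequence <- NA_character_
  expect_error(domain_to_cdna(domain_feature("site", "s", "n", 1, 1), rec2),
               "no cDNA")
})

test_that("interval length is always 3x the amino-acid length of the feature", {
  set.seed(77)
  for (k in 1:10) {
    fx <- generate_fixture(k + 300)
    recs <- attach_cdna(parse_genpept(fx$genpept_text), fx$fasta_text)
    rec <- recs[[1]]
    for (f in rec$features) {
      iv <- domain_to_cdna(f, rec)
      expect_identical(iv$cdna_end - iv$cdna_start + 1L,
                       3L * (f$aa_end - f$aa_start + 1L))
    }
  }
})

test_that("uncorrupted fixtures verify at score 1.0 everywhere; planted mismatches score (L-k)/L", {
  fx <- generate_fixture(42, n_exons = 4)
  recs <- attach_cdna(parse_genpept(fx$genpept_text), fx$fasta_text)
  rep0 <- verify_all(recs)
  expect_identical(rep0$n_perfect, rep0$n_features)
  expect_identical(rep0$n_errors, 0L)
  expect_true(all(rep0$table$score == 1))

  crp <- corrupt_cdna(fx, n = 5, seed = 8)
  recs2 <- attach_cdna(parse_genpept(fx$genpept_text), crp$fasta_text)
  rep1 <- verify_all(recs2)
  # every feature's observed score equals the planted expectation exactly
  tab <- rep1$table
  tab$feature_id <- paste0(tab$protein_id, ":", tab$kind, ":",
                           seq_len(nrow(tab)))
  merged <- merge(crp$expected, tab,
                  by.x = "feature_id", by.y = "feature_id")
  expect_identical(nrow(merged), nrow(crp$expected))
  expect_equal(merged$score, merged$expected_score)
})

test_that("empty record list yields an empty report", {
  rep <- verify_all(list())
  expect_identical(rep$n_features, 0L)
  expect_identical(nrow(rep$table), 0L)
})

test_that("shifting a computed interval off-frame lowers the verification score", {
  set.seed(13)
  n_shifted_below_1 <- 0L
  n_total <- 0L
  for (k in 1:100) {
    fx <- generate_fixture(k + 9000, n_exons = 1)
    recs <- attach_cdna(parse_genpept(fx$genpept_text), fx$fasta_text)
    rec <- recs[[1]]
    f <- rec$features[[which.max(vapply(rec$features, function(x)
      x$aa_end - x$aa_start, integer(1)))]]
    iv <- domain_to_cdna(f, rec)
    expect_identical(iv$score, 1)
    for (delta in c(-3L, -1L, 1L, 3L)) {
      s <- iv$cdna_start + delta
      e <- iv$cdna_end + delta
      if (s < 1L || e > nchar(rec$cdna_sequence)) next
      shifted <- mapping_score(iv$degenerate,
                               substr(rec$cdna_sequence, s, e))
      n_total <- n_total + 1L
      if (shifted < 1) n_shifted_below_1 <- n_shifted_below_1 + 1L
    }
  }
  # off-frame placements cannot all verify perfectly
  expect_gt(n_total, 300)
  expect_gt(n_shifted_below_1 / n_total, 0.8)
})
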