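minimal_gp <- paste(c(
  "LOCUS       NP_TEST1.1 200 aa            linear   PRI 01-JAN-2020",
  "DEFINITION  test protein.",
  "VERSION     NP_TEST1.1",
  "FEATURES             Location/Qualifiers",
  "     source          1..200",
  "                     /organism=\"test\"",
  "     Region          5..120",
  "                     /region_name=\"Kinase\"",
  "                     /note=\"protein kinase catalytic domain,",
  "                     continued on a second line\"",
  "     Site            order(10,12,15)",
  "                     /site_type=\"active\"",
  "     CDS             1..200",
  "                     /gene=\"TST1\"",
  "                     /coded_by=\"NM_TEST1.1:203..805\"",
  "ORIGIN",
  paste0("        1 ", paste(rep("mdeepqsdps", 6), collapse = " ")),
  paste0("       61 ", paste(rep("mdeepqsdps", 6), collapse = " ")),
  paste0("      121 ", paste(rep("mdeepqsdps", 6), collapse = " ")),
  paste0("      181 ", paste(rep("mdeepqsdps", 2), collapse = " ")),
  "//"), collapse = "\n")

test_that("GenPept records yield protein records with region and expanded site features", {
  recs <- parse_genpept(minimal_gp)
  expect_length(recs, 1)
  r <- recs[[1]]
  expect_identical(r$protein_id, "NP_TEST1.1")
  expect_identical(r$transcript_id, "NM_TEST1.1")
  expect_identical(r$gene_symbol, "TST1")
  expect_identical(nchar(r$aa_sequence), 200L)
  expect_identical(r$cds_start, 203L)
  expect_identical(r$cds_end, 805L)
  # 603 nt = 3*200 + stop
  expect_true(r$cds_stop_included)

  kinds <- vapply(r$features, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "region"), 1L)
  reg <- r$features[[which(kinds == "region")]]
  expect_identical(reg$aa_start, 5L)
  expect_identical(reg$aa_end, 120L)
  expect_identical(reg$name, "Kinase")
  expect_match(reg$note, "continued on a second line")

  # order(10,12,15) expands to three single-residue sites
  sites <- r$features[kinds == "site"]
  expect_length(sites, 3)
  expect_identical(vapply(sites, `[[`, integer(1), "aa_start"),
                   c(10L, 12L, 15L))
  expect_identical(vapply(sites, `[[`, integer(1), "aa_end"),
                   c(10L, 12L, 15L))
  expect_true(all(vapply(sites, `[[`, character(1), "location_raw") ==
                  "order(10,12,15)"))
  expect_true(all(vapply(sites, `[[`, character(1), "name") == "active"))
})

test_that("records without coded_by are skipped with a warning and counted", {
  no_cds <- sub("/coded_by=\"NM_TEST1.1:203..805\"", "/product=\"x\"",
                minimal_gp, fixed = TRUE)
  expect_warning(recs <- parse_genpept(no_cds), "no coded_by")
  expect_length(recs, 0)
  rep <- attr(recs, "report")
  expect_identical(rep$records_in,
                   rep$records_ok + rep$records_skipped)
  expect_identical(rep$records_skipped, 1L)
})

test_that("empty input and malformed boundaries behave as specified", {
  expect_length(parse_genpept(""), 0)
  expect_error(parse_genpept("LOCUS       X 10 aa\nFEATURES\n"),
               "unterminated record 1")
})

test_that("coded_by qualifiers parse accessions, spans and partial markers", {
  cb <- parse_coded_by("NM_000546.5:203..1384")
  expect_identical(cb$transcript_id, "NM_000546.5")
  expect_identical(cb$cds_start, 203L)
  expect_identical(cb$cds_end, 1384L)
  expect_false(cb$partial_5p || cb$partial_3p)

  cb2 <- parse_coded_by("NM_0001.1:<1..>900")
  expect_identical(cb2$cds_start, 1L)
  expect_identical(cb2$cds_end, 900L)
  expect_true(cb2$partial_5p && cb2$partial_3p)

  expect_error(parse_coded_by("garbage"), "cannot parse")
  expect_error(parse_coded_by("join(NM_1.1:1..10,NM_1.1:20..30)"),
               "unsupported")
  expect_error(parse_coded_by("complement(NM_1.1:1..10)"), "unsupported")
})

test_that("genePred rows become validated gene models", {
  txt <- paste(
    "NM_A.1\tchr1\t+\t100\t400\t2\t100,300,\t200,400,",
    "NM_B.1\tchr2\t-\t50\t950\t3\t50,300,800,\t120,420,950,",
    sep = "\n")
  models <- read_gene_models(txt)
  expect_identical(sort(names(models)), c("NM_A.1", "NM_B.1"))
  expect_identical(models$NM_A.1$exon_starts, c(100L, 300L))
  expect_identical(models$NM_A.1$exon_ends, c(200L, 400L))
  expect_identical(models$NM_B.1$strand, "-")
  # minus-strand exons still stored ascending
  expect_false(is.unsorted(models$NM_B.1$exon_starts))

  # standard 10-column layout with cdsStart/cdsEnd also accepted
  std <- "NM_C.1\tchr3\t+\t10\t90\t20\t80\t2\t10,60,\t40,90,"
  m <- read_gene_models(std)
  expect_identical(m$NM_C.1$exon_starts, c(10L, 60L))
})

test_that("bad genePred rows are rejected and duplicates keep the last row", {
  expect_warning(
    m <- read_gene_models("NM_X.1\tchr1\t+\t100\t400\t2\t100,200,\t250,400,"),
    "overlapping")
  expect_length(m, 0)
  expect_warning(
    m2 <- read_gene_models("NM_X.1\tchr1\t+\t0\t10\t2\t0,\t10,"),
    "exonCount mismatch")
  expect_length(m2, 0)
  expect_warning(
    m3 <- read_gene_models(paste(
      "NM_D.1\tchr1\t+\t0\t10\t1\t0,\t10,",
      "NM_D.1\tchr2\t+\t5\t25\t1\t5,\t25,", sep = "\n")),
    "duplicate transcript")
  expect_identical(m3$NM_D.1$chrom, "chr2")
})

test_that("cDNA attachment matches accessions and re-validates the CDS span", {
  recs <- parse_genpept(minimal_gp)
  fa_ok <- paste0(">NM_TEST1.1 some description\n",
                  paste(rep("ACGT", 250), collapse = ""))
  out <- attach_cdna(recs, fa_ok)
  expect_identical(nchar(out[[1]]$cdna_sequence), 1000L)
  expect_true(out[[1]]$valid)

  # no matching accession: sequence stays unset
  out2 <- attach_cdna(recs, ">NM_OTHER.1\nACGT")
  expect_true(is.na(out2[[1]]$cdna_sequence))
  expect_identical(attr(out2, "report")$unmatched, 1L)

  # version-insensitive fallback is applied and logged
  expect_message(out3 <- attach_cdna(recs, paste0(">NM_TEST1.2\n",
    paste(rep("ACGT", 250), collapse = ""))), "version-insensitive")
  expect_false(is.na(out3[[1]]$cdna_sequence))

  # CDS beyond the cDNA: flagged invalid
  out4 <- attach_cdna(recs, ">NM_TEST1.1\nACGTACGT")
  expect_false(out4[[1]]$valid)
  expect_match(out4[[1]]$invalid_reason, "exceeds cDNA length")
})

test_that("parsed fixture flat files preserve every feature", {
  for (seed in c(3, 14)) {
    fx <- generate_fixture(seed)
    recs <- parse_genpept(fx$genpept_text)
    expect_length(recs, 1)
    r <- recs[[1]]
    expect_identical(r$aa_sequence, fx$aa_sequence)
    expect_identical(r$cds_start, fx$cds_start)
    truth1 <- unique(fx$truth[, c("feature_id", "kind", "name",
                                  "aa_start", "aa_end")])
    got <- data.frame(
      kind = vapply(r$features, `[[`, character(1), "kind"),
      name = vapply(r$features, `[[`, character(1), "name"),
      aa_start = vapply(r$features, `[[`, integer(1), "aa_start"),
      aa_end = vapply(r$features, `[[`, integer(1), "aa_end"),
      stringsAsFactors = FALSE)
    expect_equal(got, truth1[, c("kind", "name", "aa_start", "aa_end")],
                 ignore_attr = TRUE)
  }
})
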