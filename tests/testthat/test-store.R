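# A compact hand-built input: one protein on a 2-exon gene, with a region
# spanning the junction, a site nested inside the region, and one more
# isolated site.
nested_fixture <- function() {
  model <- gene_model("NM_N.1", "chr1", "+", c(1000L, 1500L),
                      c(1090L, 1800L))
  # 90 nt exon 1; CDS starts at cDNA 10; residues 1..27 cross the junction
  # at cDNA 90/91 (residue 28 starts at cDNA 91)
  aa_len <- 50L
  set.seed(1234)
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  aa <- paste(c("M", sample(aas, aa_len - 1, replace = TRUE)), collapse = "")
  codons <- vapply(strsplit(aa, "")[[1]], function(x) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == x][1]
  }, character(1))
  cdna <- paste0(paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                       collapse = ""),
                 paste(codons, collapse = ""), "TAA",
                 paste(rep("A", transcript_length(model) - 9 - 3 * aa_len - 3),
                       collapse = ""))
  rec <- protein_record(
    "NP_N.1", "NST1", "NM_N.1", aa, 10L, 9L + 3L * aa_len + 3L,
    cdna_sequence = cdna,
    features = list(
      domain_feature("region", "Junction_dom", "spans the junction", 20, 40),
      domain_feature("site", "active", "inside the region", 25, 25),
      domain_feature("site", "phospho", "outside the region", 5, 5)))
  list(rec = rec, models = list(NM_N.1 = model))
}

test_that("one junction-spanning region yields one record per exon segment", {
  nf <- nested_fixture()
  st <- build_store(list(nf$rec), nf$models)
  r <- st$records
  reg <- r[r$kind == "region", ]
  expect_identical(nrow(reg), 2L)
  expect_identical(reg$exon_index, c(1L, 2L))
  expect_true(all(reg$score == reg$score[1]))
  expect_true(all(reg$name == "Junction_dom"))
  # 3 features -> 4 records (region split in two)
  expect_identical(store_size(st), 4L)
  expect_identical(st$report$features_mapped, 3L)
  # segment lengths sum to 3 * aa length of the region
  expect_identical(sum(reg$end - reg$start + 1L), 63L)
})

test_that("queries respect inclusive boundaries and chromosome normalization", {
  nf <- nested_fixture()
  st <- build_store(list(nf$rec), nf$models)
  r <- st$records
  for (i in seq_len(nrow(r))) {
    hit_start <- query_position(st, r$chrom[i], r$start[i])
    hit_end <- query_position(st, r$chrom[i], r$end[i])
    expect_true(i %in% hit_start$row)
    expect_true(i %in% hit_end$row)
    expect_false(i %in% query_position(st, r$chrom[i], r$start[i] - 1L)$row)
    expect_false(i %in% query_position(st, r$chrom[i], r$end[i] + 1L)$row)
  }
  # "1" and "chr1" are the same chromosome
  expect_identical(query_position(st, "1", r$start[1]),
                   query_position(st, "chr1", r$start[1]))
  expect_warning(none <- query_position(st, "chr9", 1000), "not present")
  expect_identical(nrow(none), 0L)
})

test_that("a site nested in a region is reported twice at shared positions", {
  nf <- nested_fixture()
  st <- build_store(list(nf$rec), nf$models)
  site <- st$records[st$records$name == "active", ]
  expect_identical(nrow(site), 1L)
  hits <- query_position(st, site$chrom, site$start)
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$kind, c("site", "region"))
})

test_that("empty input builds an empty store", {
  st <- build_store(list(), list())
  expect_identical(store_size(st), 0L)
  expect_identical(nrow(query_position(st, "chr1", 1)), 0L)
})

test_that("CSV, JSON and SQL exports round-trip to an identical record set", {
  fx <- generate_fixture(seed = 21, n_exons = 3)
  st <- fixture_store(fx)
  expect_gt(store_size(st), 0)
  for (fmt in c("csv", "json", "sql")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_store(st, path, fmt)
    back <- read_store(path, fmt)
    expect_equal(back$records, st$records, ignore_attr = TRUE,
                 info = fmt)
  }
})

test_that("the SQL dump executes in an embedded SQL engine with matching row count", {
  fx <- generate_fixture(seed = 33, n_exons = 2)
  st <- fixture_store(fx)
  path <- tempfile(fileext = ".sql")
  write_store(st, path, "sql")
  # independent engine: sqlite3 via the system python
  out <- system2("python", c("-c", shQuote(paste0(
    "import sqlite3,sys\n",
    "con=sqlite3.connect(':memory:')\n",
    "con.executescript(open(sys.argv[1]).read())\n",
    "print(con.execute('select count(*) from domain_records').fetchone()[0])"
  )), shQuote(path)), stdout = TRUE)
  expect_identical(as.integer(out[length(out)]), store_size(st))
})

test_that("export column order matches the published record schema", {
  fx <- generate_fixture(seed = 2)
  st <- fixture_store(fx)
  path <- tempfile(fileext = ".csv")
  write_store(st, path, "csv")
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(gsub("\"", "", hdr),
                   c("gene_symbol", "protein_id", "transcript_id", "strand",
                     "kind", "name", "score", "chrom", "start", "end",
                     "note", "exon_index"))
})
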