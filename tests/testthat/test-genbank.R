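toy_genbank <- function(path) {
  # 2000 bp, 5 features, incl. a complement-strand CDS and an
  # origin-spanning join
  lines <- c(
    "LOCUS       toy01 2000 bp    DNA     circular INV 01-JAN-2000",
    "DEFINITION  toy mitogenome fragment.",
    "FEATURES             Location/Qualifiers",
    "     source          1..2000",
    "     CDS             100..399",
    "                     /gene=\"COX1\"",
    "     tRNA            400..465",
    "                     /product=\"tRNA-Lys\"",
    "     CDS             complement(1..300)",
    "                     /gene=\"ND2\"",
    "     rRNA            500..1300",
    "                     /product=\"16S ribosomal RNA\"",
    "     CDS             join(1900..2000,1..50)",
    "                     /gene=\"CYTB\"",
    "ORIGIN",
    origin_lines(strrep("acgtacgtac", 200)),
    "//")
  writeLines(lines, path)
  path
}

test_that("a toy GenBank file parses with the documented conversions", {
  path <- toy_genbank(withr::local_tempfile(fileext = ".gb"))
  rec <- read_genbank(path, quiet = TRUE)
  expect_s3_class(rec, "mitogenome_record")
  expect_equal(rec$length, 2000L)
  expect_equal(nrow(rec$features), 5L)
  expect_length(rec$diagnostics, 0)

  f <- rec$features
  # 1-based inclusive -> 0-based half-open
  cox1 <- f[f$token == "cox1", ]
  expect_equal(c(cox1$start, cox1$end), c(99L, 399L))
  # complement 1..300 -> strand -1, start 0, end 300
  nad2 <- f[f$token == "nad2", ]
  expect_equal(c(nad2$strand, nad2$start, nad2$end), c(-1L, 0L, 300L))
  # origin-spanning join: one feature of 151 bp
  cob <- f[f$token == "cob", ]
  expect_true(cob$spans_origin)
  expect_equal(mitorder:::feature_length(cob, rec$length), 151L)
  expect_equal(f$token[f$raw_name == "tRNA-Lys"], "trnK")
  expect_equal(f$token[f$raw_name == "16S ribosomal RNA"], "rrnL")
})

test_that("reader surfaces missing, unknown and duplicated genes", {
  path <- withr::local_tempfile(fileext = ".gb")
  lines <- c(
    "LOCUS       bad01 600 bp    DNA     circular INV 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..90",
    "                     /gene=\"COX1\"",
    "     CDS             101..190",
    "                     /gene=\"COX1\"",
    "     CDS             201..290",
    "                     /gene=\"mystery protein\"",
    "ORIGIN",
    origin_lines(strrep("acgtacgtac", 60)),
    "//")
  writeLines(lines, path)
  expect_warning(
    rec <- read_genbank(path, expected_genes = c("cox1", "cob")),
    "duplicated")
  expect_true(any(grepl("unknown", rec$diagnostics)))
  expect_true(any(grepl("missing canonical gene: cob", rec$diagnostics)))
  expect_true(any(grepl("duplicated gene token: cox1", rec$diagnostics)))
})

test_that("unparseable and featureless files raise errors", {
  p1 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("this is", "not genbank"), p1)
  expect_error(read_genbank(p1), "LOCUS")
  p2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       empty 60 bp    DNA     circular INV 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "ORIGIN",
    origin_lines(strrep("acgtacgtac", 6)),
    "//"), p2)
  expect_error(read_genbank(p2), "no recognisable gene features")
})

test_that("FASTA export carries each taxon's full sequence", {
  cfg <- simulate_config(n_taxa = 3, seed = 98, lambda = 0)
  sim <- simulate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$records, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_setequal(names(back), names(sim$records))
  for (tax in names(sim$records)) {
    expect_equal(as.character(back[[tax]]), sim$records[[tax]]$sequence)
  }
})

test_that("write_genbank / read_genbank round-trips a synthetic record", {
  cfg <- simulate_config(n_taxa = 3, seed = 99, lambda = 0)
  sim <- simulate_dataset(cfg)
  rec <- sim$records[[1]]
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path, quiet = TRUE)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$length, rec$length)
  expect_equal(back$features$token, rec$features$token)
  expect_equal(back$features$start, rec$features$start)
  expect_equal(back$features$end, rec$features$end)
  expect_equal(back$features$strand, rec$features$strand)
  expect_length(back$diagnostics, 0)
})
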