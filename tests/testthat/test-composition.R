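mk_record <- function(seq, features = NULL, taxon = "cmp") {
  if (is.null(features)) {
    features <- data.frame(token = "cox1", kind = "PCG", strand = 1L,
                           start = 0L, end = nchar(seq), spans_origin = FALSE,
                           raw_name = "cox1")
  }
  mitogenome_record(taxon, seq, features)
}

test_that("base composition and skews follow their formulas", {
  bc <- base_composition("AATT")
  expect_equal(bc$at_skew, 0)
  expect_equal(bc$at_percent, 100)
  bc2 <- base_composition("AAAT")
  expect_equal(bc2$at_skew, 0.5)
  expect_equal(bc2$at_percent, 100)
  expect_equal(base_composition("GGC")$gc_skew, 1 / 3)
  expect_equal(base_composition("GCC")$gc_skew, -1 / 3)
  # zero denominator -> flagged missing
  expect_true(is.na(base_composition("GGCC")$at_skew))
  # N runs excluded from denominators
  expect_equal(base_composition("AATTNNNN")$at_percent, 100)
})

test_that("reverse complement negates skews and keeps AT%", {
  with_seed(5, {
    for (rep in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                        prob = c(0.35, 0.2, 0.1, 0.35)), collapse = "")
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      b1 <- base_composition(s); b2 <- base_composition(rc)
      expect_equal(b1$at_percent, b2$at_percent)
      expect_equal(b1$at_skew, -b2$at_skew)
      expect_equal(b1$gc_skew, -b2$gc_skew)
      expect_true(abs(b1$at_skew) <= 1 && abs(b1$gc_skew) <= 1)
    }
  })
})

test_that("unassigned fraction uses the interval union", {
  seq100 <- strrep("ACGT", 25)
  f <- data.frame(token = c("cox1", "cox2"), kind = "PCG", strand = 1L,
                  start = c(0L, 40L), end = c(40L, 80L), spans_origin = FALSE,
                  raw_name = c("cox1", "cox2"))
  expect_equal(unassigned_fraction(mk_record(seq100, f)), 20)
  # overlap counted once: 0..50 and 40..90 cover 90
  f2 <- transform(f, start = c(0L, 40L), end = c(50L, 90L))
  expect_equal(unassigned_fraction(mk_record(seq100, f2)), 10)
  # full tiling -> 0, and ur% + covered% = 100 under any feature order
  f3 <- data.frame(token = c("cox1", "cox2"), kind = "PCG", strand = 1L,
                   start = c(50L, 0L), end = c(100L, 50L), spans_origin = FALSE,
                   raw_name = c("cox1", "cox2"))
  expect_equal(unassigned_fraction(mk_record(seq100, f3)), 0)
  # origin-spanning feature contributes both arcs
  f4 <- data.frame(token = "cox1", kind = "PCG", strand = 1L, start = 90L,
                   end = 10L, spans_origin = TRUE, raw_name = "cox1")
  expect_equal(unassigned_fraction(mk_record(seq100, f4)), 80)
  # an annotated control region stays unassigned unless switched
  f5 <- rbind(f, data.frame(token = "other", kind = "other", strand = 1L,
                            start = 80L, end = 100L, spans_origin = FALSE,
                            raw_name = "D-loop"))
  expect_equal(unassigned_fraction(mk_record(seq100, f5)), 20)
  expect_equal(unassigned_fraction(mk_record(seq100, f5),
                                   count_control_region_as_gene = TRUE), 0)
})

test_that("strand usage skew is the signed length imbalance", {
  seq1k <- strrep("ACGT", 250)
  f <- data.frame(token = c("cox1", "nad5"), kind = "PCG",
                  strand = c(1L, -1L), start = c(0L, 300L),
                  end = c(700L, 600L), spans_origin = FALSE,
                  raw_name = c("cox1", "nad5"))
  expect_equal(strand_usage_skew(mk_record(seq1k, f)), 0.4)
  f$strand <- c(1L, 1L)
  expect_equal(strand_usage_skew(mk_record(seq1k, f)), 1)
  f2 <- transform(f, strand = c(1L, -1L), end = c(650L, 650L))
  expect_equal(strand_usage_skew(mk_record(seq1k, f2)), 650 / 1000 - 350 / 1000)
})

test_that("codon usage applies the stop/truncation rules", {
  expect_warning(cu <- codon_usage(mk_record("ATGCTATAA")), NA)
  expect_equal(cu[["ATG"]], 1L)
  expect_equal(cu[["CTA"]], 1L)
  expect_equal(sum(cu), 2L)  # terminal TAA excluded
  # length 8: trailing 2 nt ignored -> 2 codons
  expect_equal(sum(codon_usage(mk_record("ATGCTAGG"))), 2L)
  # additivity over two CDS
  two <- data.frame(token = c("cox1", "cox2"), kind = "PCG", strand = 1L,
                    start = c(0L, 9L), end = c(9L, 18L), spans_origin = FALSE,
                    raw_name = c("cox1", "cox2"))
  rec2 <- mk_record(paste0("ATGCTATAA", "ATGCCCTAA"), two)
  cu2 <- codon_usage(rec2)
  expect_equal(sum(cu2), 4L)
  expect_equal(cu2[["ATG"]], 2L)
  # internal stop warns with a position but is still counted
  expect_warning(cu3 <- codon_usage(mk_record("ATGTAACTAGGG")), "internal stop")
  expect_equal(cu3[["TAA"]], 1L)
  # minus-strand CDS is read on the coding strand
  fm <- data.frame(token = "cox1", kind = "PCG", strand = -1L, start = 0L,
                   end = 9L, spans_origin = FALSE, raw_name = "cox1")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGCTATAA")))
  expect_equal(codon_usage(mitogenome_record("m", rc, fm))[["CTA"]], 1L)
})

test_that("RSCU follows the equal-usage expectation", {
  # 2-codon family with counts (3, 1): Lys AAA/AAG
  cc <- stats::setNames(integer(64), names(Biostrings::getGeneticCode("5")))
  cc[c("AAA", "AAG")] <- c(3L, 1L)
  r <- rscu(cc)
  expect_equal(unname(r[c("AAA", "AAG")]), c(1.5, 0.5))
  # 4-codon family used equally -> all 1; (8,0,0,0) -> (4,0,0,0)
  cc2 <- stats::setNames(integer(64), names(cc))
  cc2[c("GGT", "GGC", "GGA", "GGG")] <- 2L
  expect_equal(unname(rscu(cc2)[c("GGT", "GGC", "GGA", "GGG")]), rep(1, 4))
  cc3 <- stats::setNames(integer(64), names(cc))
  cc3[c("GGT", "GGC", "GGA", "GGG")] <- c(8L, 0L, 0L, 0L)
  expect_equal(unname(rscu(cc3)[c("GGT", "GGC", "GGA", "GGG")]), c(4, 0, 0, 0))
})

test_that("RSCU family means are exactly 1 on simulated codon counts", {
  cfg <- simulate_config(n_taxa = 3, seed = 13, lambda = 0)
  sim <- simulate_dataset(cfg)
  code <- Biostrings::getGeneticCode("5")
  for (rec in sim$records) {
    r <- rscu(codon_usage(rec))
    fams <- split(names(r), code[names(r)])
    for (fam in fams) {
      expect_equal(mean(r[fam]), 1)
      expect_equal(sum(r[fam]), length(fam))
    }
  }
})

test_that("amino-acid frequencies sum to one", {
  cfg <- simulate_config(n_taxa = 3, seed = 14, lambda = 0)
  rec <- simulate_dataset(cfg)$records[[1]]
  af <- aa_frequencies(codon_usage(rec))
  expect_equal(sum(af), 1)
  expect_true(all(af >= 0))
})
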