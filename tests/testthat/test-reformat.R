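# Barcode/UMI trimming, header encoding and read filtering.

std_structure <- read_structure(bc1_start = 0, bc1_len = 8,
                                umi_start = 8, umi_len = 6)

mk_read <- function(name, seq, qual = strrep("I", nchar(seq))) {
  list(name = name, seq = seq, qual = qual)
}

test_that("barcode and UMI are moved from the read into the header", {
  r1 <- mk_read("p1", "ACGTACGTAAAATT")
  r2 <- mk_read("p1", "TTGGCCAATTGGCCAA")
  out <- reformat_read_pair(r1, r2, std_structure)
  expect_equal(out$status, "kept")
  expect_equal(out$record$seq, r2$seq)
  expect_equal(out$record$qual, r2$qual)
  h <- parse_read_header(out$record$name)
  expect_equal(h$barcode, "ACGTACGT")
  expect_equal(h$umi, "AAAATT")
  expect_equal(h$name, "p1")
})

test_that("low-quality barcode bases reject the pair", {
  r1 <- mk_read("p1", "ACGTACGTAAAATT",
                qual = paste0(strrep("#", 8), strrep("I", 6)))
  r2 <- mk_read("p1", "TTGGCCAATTGGCCAA")
  out <- reformat_read_pair(r1, r2, std_structure,
                            reformat_filters(min_barcode_quality = 20,
                                             max_low_quality_bases = 1))
  expect_equal(out$status, "removed_low_quality")
  # a permissive filter keeps the same pair
  out2 <- reformat_read_pair(r1, r2, std_structure,
                             reformat_filters(min_barcode_quality = 0))
  expect_equal(out2$status, "kept")
})

test_that("polyA and N-rich transcripts are rejected as low complexity", {
  r1 <- mk_read("p1", "ACGTACGTAAAATT")
  polya <- mk_read("p1", strrep("A", 50))
  out <- reformat_read_pair(r1, polya, std_structure)
  expect_equal(out$status, "removed_low_complexity")
  nrich <- mk_read("p1", paste0(strrep("N", 48), "AC"))
  expect_equal(reformat_read_pair(r1, nrich, std_structure)$status,
               "removed_low_complexity")
  # filter off keeps both
  off <- reformat_filters(complexity_filter = FALSE)
  expect_equal(reformat_read_pair(r1, polya, std_structure,
                                  off)$status, "kept")
})

test_that("reads too short for the declared structure are rejected", {
  r1 <- mk_read("p1", "ACGTACGTAA")  # only 10 bases, need 14
  r2 <- mk_read("p1", "TTGGCCAATTGGCCAA")
  out <- reformat_read_pair(r1, r2, std_structure)
  expect_equal(out$status, "removed_too_short")
})

test_that("single-read layouts take the residual suffix as transcript", {
  s <- read_structure(bc1_start = 0, bc1_len = 8, umi_start = 8,
                      umi_len = 6, umi_read = 1, transcript_read = 1)
  r1 <- mk_read("p1", paste0("ACGTACGT", "AAAATT", "GGTTCCAAGGTTCC"))
  out <- reformat_read_pair(r1, NULL, s)
  expect_equal(out$status, "kept")
  expect_equal(out$record$seq, "GGTTCCAAGGTTCC")
  expect_equal(parse_read_header(out$record$name)$umi, "AAAATT")
})

test_that("invalid read structures are rejected at construction", {
  expect_error(read_structure(bc1_start = 0, bc1_len = 8,
                              umi_start = 4, umi_len = 6),
               "overlap")
  expect_error(read_structure(bc1_len = -1, bc2_len = -1),
               "barcode")
})

test_that("reformat_fastq keeps counts, order and headers consistent", {
  sim <- fx_sim()
  out <- file.path(tempdir(), "trimmed.fastq.gz")
  stats <- reformat_fastq(sim$r1, sim$r2, out, sim$structure)
  expect_equal(stats$total_read_pairs, nrow(sim$reads))
  expect_equal(stats$kept +
                 stats$removed_low_quality +
                 stats$removed_low_complexity +
                 stats$removed_too_short,
               stats$total_read_pairs)
  expect_equal(stats$kept, nrow(sim$reads))
  fq <- ShortRead::readFastq(out)
  h <- parse_read_header(as.character(ShortRead::id(fq)))
  # round trip: headers carry the exact observed barcode and UMI,
  # in input order
  expect_equal(h$barcode, sim$reads$barcode_obs)
  expect_equal(h$umi, sim$reads$umi)
  expect_equal(h$name, sim$reads$name)
})

test_that("reformatting is byte-deterministic and handles empty input", {
  sim <- fx_sim()
  o1 <- file.path(tempdir(), "det1.fastq")
  o2 <- file.path(tempdir(), "det2.fastq")
  reformat_fastq(sim$r1, sim$r2, o1, sim$structure)
  reformat_fastq(sim$r1, sim$r2, o2, sim$structure)
  expect_equal(tools::md5sum(o1)[[1]], tools::md5sum(o2)[[1]])

  empty <- file.path(tempdir(), "empty.fastq")
  writeLines(character(0), empty)
  stats <- reformat_fastq(empty, NULL, file.path(tempdir(), "eo.fastq"),
                          read_structure(bc1_start = 0, bc1_len = 8,
                                         umi_start = 8, umi_len = 6,
                                         transcript_read = 1))
  expect_equal(stats$total_read_pairs, 0L)
  expect_equal(stats$kept, 0L)
  expect_true(file.exists(file.path(tempdir(), "eo.fastq")))
})

test_that("mismatched mate counts raise a hard error naming both files", {
  sim <- fx_sim()
  short <- file.path(tempdir(), "short_r2.fastq")
  fq <- ShortRead::readFastq(sim$r2)
  ShortRead::writeFastq(fq[1:10], short, compress = FALSE)
  expect_error(
    reformat_fastq(sim$r1, short, file.path(tempdir(), "mm.fastq"),
                   sim$structure),
    "read counts differ")
})
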