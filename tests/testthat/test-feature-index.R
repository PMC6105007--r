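# Binned interval index construction and alignment assignment.

toy_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

two_exon_gtf <- toy_gtf(c(
  'chr1\ttoy\texon\t101\t200\t.\t+\t.\tgene_id "g1";',
  'chr1\ttoy\texon\t301\t400\t.\t+\t.\tgene_id "g1";'
))

test_that("a two-exon gene lands in one bin with the right gene body", {
  idx <- build_feature_index(two_exon_gtf, bin_width = 1000)
  expect_s3_class(idx, "feature_index")
  expect_equal(unique(idx$exon_bins$bin), 0L)
  expect_equal(nrow(idx$exon_bins), 2L)
  # gene body [100, 400) in 0-based half-open coordinates
  expect_equal(idx$gene_bins$start, 100L)
  expect_equal(idx$gene_bins$end, 400L)
})

test_that("an exon spanning a bin boundary is present in both bins", {
  gtf <- toy_gtf('chr1\ttoy\texon\t951\t1050\t.\t+\t.\tgene_id "g1";')
  idx <- build_feature_index(gtf, bin_width = 1000)
  expect_setequal(idx$exon_bins$bin, c(0L, 1L))
})

test_that("exons without a gene_id attribute are a hard error", {
  gtf <- toy_gtf('chr1\ttoy\texon\t101\t200\t.\t+\t.\tfoo "bar";')
  expect_error(build_feature_index(gtf), "gene_id")
})

test_that("single alignments are classified with the documented rules", {
  idx <- build_feature_index(two_exon_gtf, bin_width = 1000)
  r <- assign_alignment("chr1", 120, "50M", idx)
  expect_equal(r$status, "exon")
  expect_equal(r$gene_id, "g1")
  # between the two exons: inside the gene body but off-exon
  expect_equal(assign_alignment("chr1", 210, "80M", idx)$status,
               "intron")
  # spliced read whose M blocks hit both exons of the same gene
  expect_equal(assign_alignment("chr1", 150, "50M100N50M", idx)$status,
               "exon")
  # off-gene and unmapped records
  expect_equal(assign_alignment("chr1", 2000, "50M", idx)$status,
               "aligned_elsewhere")
  expect_equal(assign_alignment("chr1", 0, "50M", idx,
                                unmapped = TRUE)$status, "unaligned")
  expect_equal(assign_alignment("ERCC-0001", 10, "50M", idx)$status,
               "ercc")
  expect_equal(assign_alignment("ERCC-0001", 10, "50M",
                                idx)$gene_id, "ERCC-0001")
})

test_that("overlapping genes make a shared-window read ambiguous", {
  gtf <- toy_gtf(c(
    'chr1\ttoy\texon\t101\t400\t.\t+\t.\tgene_id "gA";',
    'chr1\ttoy\texon\t301\t600\t.\t+\t.\tgene_id "gB";'
  ))
  idx <- build_feature_index(gtf, bin_width = 1000)
  expect_equal(assign_alignment("chr1", 320, "50M", idx)$status,
               "ambiguous")
  expect_equal(assign_alignment("chr1", 120, "50M", idx)$gene_id, "gA")
})

test_that("random query intervals agree with the naive scan oracle", {
  aln <- fx_aln()
  tabs <- oracle_annotation_tables(aln$gtf)
  idx <- build_feature_index(aln$gtf, bin_width = 1000)
  chroms <- c("chr1", "chr2", "MT", "ERCC-0001")
  lens <- aln$annotation$contig_lengths[chroms]
  set.seed(123)
  for (i in seq_len(300)) {
    chrom <- sample(chroms, 1L)
    w <- sample(20:200, 1L)
    p <- sample.int(max(1L, lens[[chrom]] - w), 1L) - 1L
    got <- assign_alignment(chrom, p, paste0(w, "M"), idx)
    want <- oracle_assign(chrom, p, p + w, tabs)
    expect_equal(got$status, want$status,
                 info = sprintf("%s:%d-%d", chrom, p, p + w))
    if (want$status %in% c("exon", "ercc")) {
      expect_equal(got$gene_id, unname(want$gene_id))
    }
  }
})

test_that("tag_bam writes BC/OX/GE/YS tags matching generator truth", {
  aln <- fx_aln()
  idx <- build_feature_index(aln$gtf, bin_width = 1000)
  out <- file.path(tempdir(), "tagged_aln.bam")
  stats <- suppressWarnings(tag_bam(aln$bam, idx, out))
  # per-status counts equal the generator truth exactly
  want <- table(aln$truth$status)
  for (s in names(want)) {
    expect_equal(stats[[s]], unname(want[[s]]), info = s)
  }
  # partition: statuses sum to the primary-alignment count
  expect_equal(stats$exon + stats$intron + stats$ambiguous +
                 stats$aligned_elsewhere + stats$unaligned +
                 stats$ercc,
               nrow(aln$truth))
  rec <- scpreproc:::read_tagged_bam(out)
  expect_true(all(rec$barcode == "ACGTACGT"))
  expect_true(all(rec$umi == "AACCGG"))
  tr <- aln$truth
  tr$qname <- paste0("ACGTACGT_AACCGG#", tr$name)
  m <- merge(as.data.frame(rec), tr, by = "qname")
  expect_equal(nrow(m), nrow(aln$truth))
  expect_equal(m$status.x, m$status.y)
  genes <- m$status.y %in% c("exon", "ercc")
  expect_equal(m$gene_id.x[genes], m$gene_id.y[genes])
})

test_that("bin width changes speed, never results", {
  aln <- fx_aln()
  tagged <- lapply(c(500, 10000, 1000000), function(bw) {
    idx <- build_feature_index(aln$gtf, bin_width = bw)
    out <- file.path(tempdir(), sprintf("tagged_bw%d.bam", bw))
    tag_bam(aln$bam, idx, out)
    scpreproc:::read_tagged_bam(out)[, .(qname, status, gene_id)]
  })
  expect_identical(tagged[[1]], tagged[[2]])
  expect_identical(tagged[[2]], tagged[[3]])
})

test_that("tagging the same BAM twice is byte-identical", {
  aln <- fx_aln()
  idx <- build_feature_index(aln$gtf, bin_width = 1000)
  o1 <- file.path(tempdir(), "det_a.bam")
  o2 <- file.path(tempdir(), "det_b.bam")
  tag_bam(aln$bam, idx, o1)
  tag_bam(aln$bam, idx, o2)
  expect_equal(tools::md5sum(o1)[[1]], tools::md5sum(o2)[[1]])
})
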