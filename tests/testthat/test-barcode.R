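# Whitelist matching, enriched-barcode detection and demultiplexing.

wl2 <- data.frame(cell_id = c("c1", "c2"),
                  barcode = c("ACGT", "TTTT"),
                  stringsAsFactors = FALSE)

test_that("whitelist matching follows the minimal-distance rule", {
  m <- match_barcode(c("ACGT", "ACGA", "AGGA", "TTTA"), wl2,
                     max_mismatch = 1)
  expect_equal(m$cell_id, c("c1", "c1", NA, "c2"))
  expect_equal(m$category,
               c("exact_match", "mismatch_match", "unmatched",
                 "mismatch_match"))
  expect_equal(m$distance, c(0L, 1L, NA, 1L))
})

test_that("equidistant matches are left unassigned as ambiguous", {
  wl <- data.frame(cell_id = c("c1", "c2"),
                   barcode = c("ACGT", "ACTA"))
  m <- match_barcode("ACTT", wl, max_mismatch = 1)
  expect_true(is.na(m$cell_id))
  expect_equal(m$category, "ambiguous")
  expect_equal(m$distance, 1L)
})

test_that("a barcode length mismatch is a hard error", {
  expect_error(match_barcode("ACGTA", wl2), "length")
})

test_that("enriched barcodes are recovered despite error variants", {
  for (seed in 1:3) {
    set.seed(seed)
    true_bc <- generate_barcodes(8, len = 8, min_dist = 4,
                                 seed = seed)
    counts <- sample(200:1500, 8)
    obs <- rep(true_bc, counts)
    # hamming-1 error variants at <= 1% of the parent abundance
    for (i in seq_along(true_bc)) {
      v <- scpreproc:::mutate_base(true_bc[i], sample(8, 1))
      obs <- c(obs, rep(v, max(1, floor(0.01 * counts[i]))))
    }
    obs <- sample(obs)
    det <- detect_barcodes(obs, mode = "top_n", n_or_cutoff = 8)
    expect_setequal(det$barcode, true_bc)
    # folded counts include the error variants
    expect_equal(sum(det$count), length(obs))
  }
})

test_that("detection handles a single barcode and min_count mode", {
  det <- detect_barcodes(rep("ACGTACGT", 57), mode = "top_n",
                         n_or_cutoff = 1)
  expect_equal(det$barcode, "ACGTACGT")
  expect_equal(det$count, 57L)
  expect_warning(detect_barcodes(rep("ACGTACGT", 5), n_or_cutoff = 3),
                 "only")
  obs <- c(rep("AAAAAAAA", 100), rep("CCCCCCCC", 40),
           rep("GGGGGGGG", 9))
  det <- detect_barcodes(obs, mode = "min_count", n_or_cutoff = 10)
  expect_setequal(det$barcode, c("AAAAAAAA", "CCCCCCCC"))
})

test_that("detection is independent of read order", {
  set.seed(5)
  obs <- c(rep("AACCGGTT", 300), rep("AACCGGTA", 3),
           rep("TTGGCCAA", 200), rep("GATCGATC", 150))
  d1 <- detect_barcodes(obs, mode = "top_n", n_or_cutoff = 3)
  d2 <- detect_barcodes(rev(obs), mode = "top_n", n_or_cutoff = 3)
  d3 <- detect_barcodes(sample(obs), mode = "top_n", n_or_cutoff = 3)
  expect_identical(d1, d2)
  expect_identical(d1, d3)
})

test_that("error-free reads demultiplex exactly to their true cells", {
  run <- fx_run()
  sim <- fx_sim()
  d <- run$demux
  total <- sum(unlist(d$stats))
  expect_equal(d$stats$exact_match, nrow(sim$reads))
  expect_equal(total, nrow(sim$reads))
  # per-cell tables partition the exon/ercc reads
  want <- table(sim$reads$cell_id[sim$reads$status %in%
                                    c("exon", "ercc")])
  got <- stats::setNames(d$manifest$n_rows, d$manifest$cell_id)
  expect_equal(got[names(want)], unlist(as.list(want)),
               ignore_attr = TRUE)
  expect_equal(sum(d$manifest$n_rows), sum(want))
})

test_that("per-cell tables carry gene, UMI and position per read", {
  run <- fx_run()
  sim <- fx_sim()
  man <- run$demux$manifest
  i <- which(man$n_rows > 0)[1]
  tab <- read.csv(file.path(run$out_dir, man$file[i]))
  expect_named(tab, c("gene_id", "umi", "position"))
  truth <- sim$reads[sim$reads$cell_id == man$cell_id[i] &
                       sim$reads$status %in% c("exon", "ercc"), ]
  expect_setequal(paste(tab$gene_id, tab$umi, tab$position),
                  paste(truth$gene_id, truth$umi, truth$pos))
})

test_that("missing tags are hard errors", {
  run <- fx_run()
  sim <- fx_sim()
  # the untagged aligner BAM has no BC tag yet
  expect_error(
    demultiplex(sim$bam, sim$barcodes,
                file.path(tempdir(), "dmx_err")),
    "BC tag")
})
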