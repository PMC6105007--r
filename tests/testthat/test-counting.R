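# Greedy UMI deduplication and gene count matrix assembly.

test_that("the fold rule merges only dominated near-duplicates", {
  # distance 1 and 10 > 2 x 3: folded
  expect_equal(dedup_umis(c(AAAA = 10L, AAAT = 3L))$molecules, 1L)
  # strict 'more than twice': 4 <= 2 x 3 and 6 == 2 x 3 both retained
  expect_equal(dedup_umis(c(AAAA = 4L, AAAT = 3L))$molecules, 2L)
  expect_equal(dedup_umis(c(AAAA = 6L, AAAT = 3L))$molecules, 2L)
  expect_equal(dedup_umis(c(AAAA = 7L, AAAT = 3L))$molecules, 1L)
  # distance 4 > 1: never folded
  expect_equal(dedup_umis(c(AAAA = 10L, TTTT = 9L))$molecules, 2L)
  # singleton
  expect_equal(dedup_umis(c(AAAA = 5L))$molecules, 1L)
})

test_that("the merge map conserves all input UMIs and counts", {
  r <- dedup_umis(c(AAAA = 10L, AAAT = 3L, AATT = 1L, GGGG = 2L))
  expect_equal(nrow(r$merge_map), 4L)
  expect_equal(sum(r$merge_map$count), 16L)
  expect_equal(sum(r$retained), 16L)
  expect_equal(r$molecules, length(r$retained))
  # no chaining: every fold target is itself retained
  expect_true(all(r$merge_map$into %in% names(r$retained)))
})

test_that("greedy dedup equals the brute-force fixed-point oracle", {
  set.seed(99)
  for (i in seq_len(300)) {
    u <- random_umi_set()
    expect_equal(dedup_umis(u)$molecules, oracle_dedup(u),
                 info = paste(names(u), u, collapse = " "))
  }
})

test_that("adding reads or novel UMIs moves counts as expected", {
  set.seed(7)
  for (i in seq_len(50)) {
    u <- random_umi_set()
    base <- dedup_umis(u)$molecules
    # an extra read on an existing UMI never increases molecules
    j <- sample(length(u), 1L)
    u2 <- u
    u2[j] <- u2[j] + 1L
    expect_lte(dedup_umis(u2)$molecules, base + 0L)
    # a brand-new UMI beyond max_hamming adds exactly one molecule
    far <- names(u)[1L]
    far <- chartr("ACGT", "GTAC", far)   # distance = length > 1
    if (!far %in% names(u) &&
        min(hamming_distance(rep(far, length(u)), names(u))) > 1L) {
      u3 <- c(u, stats::setNames(3L, far))
      expect_equal(dedup_umis(u3)$molecules, base + 1L)
    }
  }
})

test_that("mixed UMI lengths are a hard error", {
  expect_error(dedup_umis(c(AAAA = 2L, AAAAA = 1L)), "length")
})

test_that("counting recovers the simulated molecule table exactly", {
  run <- fx_run()
  sim <- fx_sim()
  m <- run$counts$matrix
  tm <- truth_matrix(sim, rownames(m), colnames(m))
  expect_identical(m, tm)
  ds <- run$counts$dedup_stats
  expect_true(all(ds$umis_corrected ==
                    ds$distinct_umis - ds$molecules_out))
  expect_true(all(ds$umis_corrected >= 0L))
  # molecules <= distinct UMIs <= reads, per cell
  expect_true(all(ds$molecules_out <= ds$distinct_umis))
  expect_true(all(ds$distinct_umis <= ds$reads_in))
})

test_that("without duplication the matrix equals raw read counts", {
  sim <- simulate_experiment(file.path(tempdir(), "nodup"),
                             n_cells = 6, n_genes = 5, n_ercc = 2,
                             dup_range = c(1L, 1L),
                             umi_errors = FALSE, seed = 3)
  idx <- build_feature_index(sim$gtf)
  tb <- file.path(tempdir(), "nodup_tag.bam")
  tag_bam(sim$bam, idx, tb)
  dmx_dir <- file.path(tempdir(), "nodup_dmx")
  demultiplex(tb, sim$barcodes, dmx_dir)
  cnt <- count_genes(dmx_dir, index_gene_ids(idx))
  reads <- sim$reads[sim$reads$status %in% c("exon", "ercc"), ]
  want <- table(factor(reads$gene_id, rownames(cnt$matrix)),
                factor(reads$cell_id, colnames(cnt$matrix)))
  expect_equal(unname(cnt$matrix), unname(unclass(want)),
               ignore_attr = TRUE)
  # non-UMI mode on the same tables gives read counts too
  cnt2 <- count_genes(dmx_dir, index_gene_ids(idx), has_umi = FALSE)
  expect_identical(cnt2$matrix, cnt$matrix)
})

test_that("unknown gene ids in a table are a hard error", {
  d <- file.path(tempdir(), "badgene")
  dir.create(file.path(d, "cells"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(data.frame(cell_id = "c1", barcode = "ACGT",
                       file = "cells/c1.csv", n_rows = 1),
            file.path(d, "cell_manifest.csv"), row.names = FALSE)
  write.csv(data.frame(gene_id = "ghost", umi = "AAAA", position = 1),
            file.path(d, "cells/c1.csv"), row.names = FALSE)
  expect_error(count_genes(d, gene_ids = c("g1", "g2")), "ghost")
})

test_that("matrix round trips through CSV and MatrixMarket", {
  run <- fx_run()
  m <- run$counts$matrix
  expect_identical(read_count_matrix(run$out_dir), m)
  csv <- read.csv(file.path(run$out_dir, "gene_count.csv"),
                  row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(csv), m, ignore_attr = TRUE)
})
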