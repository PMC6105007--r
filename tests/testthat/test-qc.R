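# QC metric aggregation and the three-stage outlier detector.

qc_metrics3 <- c("log10_molecules", "genes_detected", "pct_mito")

test_that("the QC table matches per-cell generator truth", {
  run <- fx_run()
  sim <- fx_sim()
  qc <- run$qc
  expect_equal(nrow(qc), 24L)
  # total reads per cell: every matched read of that cell
  want_reads <- table(sim$reads$cell_id)
  expect_equal(qc$total_reads,
               as.integer(want_reads[qc$cell_id]))
  # molecules per cell from the truth table
  want_mol <- tapply(sim$molecules$molecules, sim$molecules$cell_id,
                     sum)
  expect_equal(qc$molecules, as.integer(want_mol[qc$cell_id]))
  # mapping percentages partition each cell's reads
  pct <- qc[, grep("^pct_mapped_", names(qc))]
  expect_equal(rowSums(pct), rep(100, nrow(qc)), tolerance = 1e-9)
  # mito percentage reflects MT-gene counts
  mito_truth <- sim$molecules[grepl("^mt-", sim$molecules$gene_id), ]
  want_mito <- tapply(mito_truth$molecules, mito_truth$cell_id, sum)
  want_mito <- as.numeric(want_mito[qc$cell_id])
  want_mito[is.na(want_mito)] <- 0
  want_mito <- 100 * want_mito / qc$molecules
  expect_equal(qc$pct_mito, want_mito, tolerance = 1e-9)
  # spike-in recovery present and within [0, 1]
  expect_true(all(qc$ercc_recovery >= 0 & qc$ercc_recovery <= 1))
})

test_that("annotations without spike-ins drop the ercc columns", {
  d <- file.path(tempdir(), "noercc")
  sim <- simulate_experiment(d, n_cells = 6, n_genes = 5, n_ercc = 0,
                             lambda_ercc = 0, seed = 5)
  idx <- build_feature_index(sim$gtf)
  tb <- file.path(tempdir(), "noercc.bam")
  tag_bam(sim$bam, idx, tb)
  dmx <- demultiplex(tb, sim$barcodes, file.path(d, "dmx"))
  cnt <- count_genes(file.path(d, "dmx"), index_gene_ids(idx))
  qc <- compute_qc_table(dmx$cell_stats, cnt$dedup_stats,
                         cnt$matrix, idx)
  expect_false("ercc_recovery" %in% names(qc))
  expect_false("pct_counts_ercc" %in% names(qc))
})

test_that("mismatched cell sets across inputs are a hard error", {
  run <- fx_run()
  idx <- build_feature_index(fx_sim()$gtf)
  cs <- run$demux$cell_stats[-1, ]
  expect_error(
    compute_qc_table(cs, run$counts$dedup_stats, run$counts$matrix,
                     idx),
    "cell sets differ")
})

test_that("mahalanobis distance matches its closed forms", {
  # identity covariance: squared euclidean distance
  set.seed(2)
  x <- matrix(rnorm(60), ncol = 3)
  d2 <- qc_mahalanobis(x, c(0, 0, 0), diag(3))
  expect_equal(d2, rowSums(x^2), tolerance = 1e-10)
  # 1-D case: (x - mu)^2 / sigma^2
  expect_equal(qc_mahalanobis(matrix(3), 1, matrix(4)), 1,
               tolerance = 1e-7, ignore_attr = TRUE)
  # 2-D worked case against an independent linear solve
  S <- matrix(c(2, 0, 0, 1), 2)
  v <- c(1, 2)
  expect_equal(qc_mahalanobis(v, c(0, 0), S), 4.5, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(unname(qc_mahalanobis(v, c(0, 0), S)),
               drop(t(v) %*% solve(S, v)), tolerance = 1e-7)
})

test_that("a clean Gaussian population is flagged near the nominal rate", {
  fr <- vapply(1:3, function(s) {
    sim <- simulate_qc_table(2000, poor_fraction = 0, seed = s)
    oc <- detect_outliers(sim$qc, metrics = qc_metrics3, comp = 1,
                          conf = 0.99, seed = s)
    mean(oc$is_outlier)
  }, numeric(1))
  expect_true(all(fr >= 0.005 & fr <= 0.02))
})

test_that("a shifted poor-cell component is found with comp = 2", {
  for (s in 1:2) {
    sim <- simulate_qc_table(2000, poor_fraction = 0.1, shift_sd = 3,
                             seed = 100 + s)
    oc <- detect_outliers(sim$qc, metrics = qc_metrics3, comp = 2,
                          conf = 0.99, seed = s)
    expect_gte(mean(oc$is_outlier[sim$truth]), 0.90)
    expect_gte(mean(!oc$is_outlier[!sim$truth]), 0.95)
    # flagged poor cells come mostly from the low-quality component
    expect_true(sum(oc$stage == "low_component", na.rm = TRUE) >
                  0.5 * sum(sim$truth))
  }
})

test_that("every cell receives exactly one call and a stage when flagged", {
  sim <- simulate_qc_table(500, poor_fraction = 0.1, seed = 8)
  oc <- detect_outliers(sim$qc, metrics = qc_metrics3, comp = 2,
                        seed = 8)
  expect_equal(nrow(oc), 500L)
  expect_false(any(duplicated(oc$cell_id)))
  expect_true(all(!oc$is_outlier | oc$stage %in%
                    c("pre_filter", "low_component", "distance")))
  expect_true(all(is.na(oc$stage[!oc$is_outlier])))
})

test_that("calls are invariant to cell order and metric rescaling", {
  sim <- simulate_qc_table(800, poor_fraction = 0.1, seed = 21)
  base <- detect_outliers(sim$qc, metrics = qc_metrics3, comp = 2,
                          seed = 4)
  perm <- sample(nrow(sim$qc))
  shuffled <- detect_outliers(sim$qc[perm, ], metrics = qc_metrics3,
                              comp = 2, seed = 4)
  expect_equal(shuffled$is_outlier[order(perm)], base$is_outlier)
  rescaled <- sim$qc
  rescaled$genes_detected <- rescaled$genes_detected * 1000 + 5
  again <- detect_outliers(rescaled, metrics = qc_metrics3, comp = 2,
                           seed = 4)
  expect_equal(again$is_outlier, base$is_outlier)
  expect_equal(again$mahalanobis_distance, base$mahalanobis_distance,
               tolerance = 1e-8)
})

test_that("degenerate metrics fail loudly", {
  sim <- simulate_qc_table(200, seed = 3)
  qc <- sim$qc
  qc$flat <- 1
  expect_error(
    detect_outliers(qc, metrics = c(qc_metrics3, "flat")),
    "singular|constant")
  expect_error(detect_outliers(qc, metrics = c("nope")), "nope")
  expect_error(detect_outliers(qc[1:4, ], metrics = qc_metrics3),
               "at least")
})
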