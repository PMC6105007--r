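# QC plots and the standalone HTML report.

test_that("demux and mapping plots render from stats objects", {
  run <- fx_run()
  p1 <- plot_demux_stats(run$demux$stats)
  expect_s3_class(p1, "ggplot")
  # empty stats still build a figure
  p0 <- plot_demux_stats(data.frame(metric = character(),
                                    value = integer()))
  expect_s3_class(p0, "ggplot")
  p2 <- plot_mapping_rates(run$demux$cell_stats)
  expect_s3_class(p2, "ggplot")
  b <- ggplot2::ggplot_build(p2)
  # stacked fractions sum to 1 for every cell
  ysum <- tapply(b$data[[1]]$ymax - b$data[[1]]$ymin,
                 b$data[[1]]$x, sum)
  expect_true(all(abs(ysum - 1) < 1e-9))
  # single-cell edge case
  one <- run$demux$cell_stats[1, , drop = FALSE]
  expect_s3_class(plot_mapping_rates(one), "ggplot")
})

test_that("cells are ordered by decreasing exon mapping rate", {
  run <- fx_run()
  cs <- run$demux$cell_stats
  p <- plot_mapping_rates(cs)
  lev <- levels(ggplot2::ggplot_build(p)$plot$data$cell_id)
  rate <- cs$exon / rowSums(cs[, intersect(
    c("exon", "intron", "ambiguous", "aligned_elsewhere",
      "unaligned", "ercc"), names(cs))])
  expect_equal(lev, cs$cell_id[order(-rate, cs$cell_id)])
})

test_that("the QC pair plot shows one panel per metric pair", {
  run <- fx_run()
  metrics <- c("log10_molecules", "genes_detected", "pct_mito")
  p <- plot_qc_pairs(run$qc, run$outliers, metrics = metrics)
  b <- ggplot2::ggplot_build(p)
  expect_equal(length(unique(b$layout$layout$panel)), choose(3, 2))
})

test_that("the report is standalone, complete and non-destructive", {
  run <- fx_run()
  report <- file.path(run$out_dir, "report.html")
  expect_true(file.exists(report))
  before <- tools::md5sum(file.path(run$out_dir, "gene_count.csv"))
  html <- paste(readLines(report), collapse = "\n")
  for (sec in c("Run parameters", "FASTQ reformatting",
                "Barcode demultiplexing", "Per-cell mapping rates",
                "UMI deduplication", "Quality control",
                "Dimension reduction")) {
    expect_match(html, sec, fixed = TRUE, info = sec)
  }
  # images are embedded data URIs; no external asset references
  expect_match(html, "src='data:image/png;base64,")
  expect_false(grepl("src=['\"]https?:", html))
  expect_match(html, "<!DOCTYPE html>", fixed = TRUE)
  # regenerating the report does not touch pipeline outputs
  create_report(run$out_dir,
                report_file = file.path(tempdir(), "report2.html"))
  expect_identical(tools::md5sum(
    file.path(run$out_dir, "gene_count.csv")), before)
})

test_that("a partial run renders with explicit stage notices", {
  d <- file.path(tempdir(), "partial_run")
  dir.create(d, showWarnings = FALSE)
  write_stats_csv(fx_run()$reformat_stats,
                  file.path(d, "reformat_stats.csv"))
  out <- create_report(d, report_file = file.path(d, "r.html"))
  html <- paste(readLines(out), collapse = "\n")
  expect_match(html, "stage not run")
  expect_match(html, "FASTQ reformatting")
})
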