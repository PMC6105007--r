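# Standalone HTML QC report. All numbers shown are re-read from the
# stage CSV files in the run directory (the single source of truth);
# figures are embedded as data URIs so the report is a single
# shippable file with no external assets.

#' Append an entry to the run manifest
#'
#' Every pipeline stage records the parameters it ran with, its main
#' input/output paths, the package version and a timestamp in
#' `run_manifest.csv` inside the run directory. The report reproduces
#' this table verbatim.
#'
#' @param out_dir run directory.
#' @param stage stage name.
#' @param params named list of parameters (flattened to `k=v`).
#' @param inputs,outputs character vectors of paths.
#' @return The manifest path, invisibly.
#' @export
append_manifest <- function(out_dir, stage, params = list(),
                            inputs = character(),
                            outputs = character()) {
  entry <- data.frame(
    stage = stage,
    parameters = paste(names(params),
                       vapply(params, function(p)
                         paste(format(p), collapse = " "),
                         character(1)),
                       sep = "=", collapse = "; "),
    inputs = paste(inputs, collapse = "; "),
    outputs = paste(outputs, collapse = "; "),
    version = as.character(utils::packageVersion("scpreproc")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    stringsAsFactors = FALSE)
  path <- file.path(out_dir, "run_manifest.csv")
  if (file.exists(path)) {
    old <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    entry <- rbind(old, entry)
  }
  utils::write.csv(entry, path, row.names = FALSE)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 30L) {
  if (nrow(df) > max_rows) {
    note <- sprintf("<p class='note'>first %d of %d rows shown</p>",
                    max_rows, nrow(df))
    df <- utils::head(df, max_rows)
  } else note <- ""
  fmt <- function(v) {
    if (is.numeric(v)) format(round(v, 3L), trim = TRUE) else
      html_escape(as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)),
                                "</th>", collapse = ""), "</tr>")
  rows <- apply(cells, 1L, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>", head, paste(rows, collapse = ""), "</table>",
         note)
}

fig_data_uri <- function(plot, width = 7, height = 4.5) {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f), add = TRUE)
  ggplot2::ggsave(f, plot, width = width, height = height, dpi = 110)
  base64enc::dataURI(file = f, mime = "image/png")
}

section <- function(title, body) {
  paste0("<section><h2>", html_escape(title), "</h2>", body,
         "</section>")
}

missing_stage <- function(what) {
  sprintf("<p class='note'>stage not run: %s not found</p>",
          html_escape(what))
}

read_if <- function(path) {
  if (file.exists(path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else NULL
}

#' Create a standalone HTML QC report for a run directory
#'
#' Collects the outputs of whichever pipeline stages have run in
#' `out_dir` -- reformatting, demultiplexing, mapping, deduplication,
#' QC metrics and outlier detection -- and writes a single
#' self-contained HTML file with the run parameters, per-stage
#' statistics, the standard QC figures and a PCA of the log-counts
#' (top 500 most variable genes). Stages that have not run are shown
#' with an explicit notice instead of failing, and generating the
#' report never modifies any pipeline output.
#'
#' @param out_dir a pipeline run directory.
#' @param report_file output path (default `report.html` inside
#'   `out_dir`).
#' @return The report path, invisibly.
#' @export
create_report <- function(out_dir,
                          report_file = file.path(out_dir,
                                                  "report.html")) {
  parts <- character(0)

  manifest <- read_if(file.path(out_dir, "run_manifest.csv"))
  parts <- c(parts, section(
    "Run parameters",
    if (is.null(manifest)) missing_stage("run_manifest.csv") else
      html_table(manifest)))

  ref <- read_if(file.path(out_dir, "reformat_stats.csv"))
  parts <- c(parts, section(
    "FASTQ reformatting",
    if (is.null(ref)) missing_stage("reformat_stats.csv") else
      html_table(ref)))

  dmx <- read_if(file.path(out_dir, "demux_stats.csv"))
  parts <- c(parts, section(
    "Barcode demultiplexing",
    if (is.null(dmx)) missing_stage("demux_stats.csv") else
      paste0(html_table(dmx),
             sprintf("<img src='%s' alt='barcode matching'/>",
                     fig_data_uri(plot_demux_stats(dmx))))))

  cms <- read_if(file.path(out_dir, "cell_mapping_stats.csv"))
  parts <- c(parts, section(
    "Per-cell mapping rates",
    if (is.null(cms)) missing_stage("cell_mapping_stats.csv") else
      sprintf("<img src='%s' alt='mapping rates'/>",
              fig_data_uri(plot_mapping_rates(cms)))))

  dd <- read_if(file.path(out_dir, "dedup_stats.csv"))
  parts <- c(parts, section(
    "UMI deduplication",
    if (is.null(dd)) missing_stage("dedup_stats.csv") else
      html_table(data.frame(
        metric = c("cells", "reads in", "distinct UMIs",
                   "molecules out", "UMIs corrected"),
        value = c(nrow(dd), sum(dd$reads_in), sum(dd$distinct_umis),
                  sum(dd$molecules_out), sum(dd$umis_corrected))))))

  qc <- read_if(file.path(out_dir, "qc_metrics.csv"))
  out <- read_if(file.path(out_dir, "outliers.csv"))
  qc_body <- if (is.null(qc)) {
    missing_stage("qc_metrics.csv")
  } else {
    b <- html_table(utils::head(qc, 15L))
    if (!is.null(out)) {
      n_out <- sum(out$is_outlier)
      b <- paste0(
        b,
        sprintf("<p>%d of %d cells flagged as outliers (%s)</p>",
                n_out, nrow(out),
                paste(names(table(out$stage)),
                      table(out$stage), sep = ": ",
                      collapse = ", ")),
        sprintf("<img src='%s' alt='QC pairs'/>",
                fig_data_uri(plot_qc_pairs(qc, out),
                             width = 8, height = 6)))
    }
    b
  }
  parts <- c(parts, section("Quality control", qc_body))

  mtx_path <- file.path(out_dir, "gene_count.mtx")
  pca_body <- if (!file.exists(mtx_path)) {
    missing_stage("gene_count.mtx")
  } else {
    mat <- read_count_matrix(out_dir)
    lg <- log1p(mat)
    v <- apply(lg, 1L, stats::var)
    topg <- order(-v)[seq_len(min(500L, nrow(lg)))]
    pc <- stats::prcomp(t(lg[topg, , drop = FALSE]), center = TRUE)
    df <- data.frame(PC1 = pc$x[, 1L],
                     PC2 = if (ncol(pc$x) > 1L) pc$x[, 2L] else 0,
                     outlier = if (is.null(out)) FALSE else
                       out$is_outlier[match(colnames(mat),
                                            out$cell_id)])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1,
                                          y = .data$PC2,
                                          colour = .data$outlier)) +
      ggplot2::geom_point() +
      ggplot2::scale_colour_manual(
        values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
      ggplot2::labs(title = "PCA of log1p counts") +
      ggplot2::theme_minimal()
    sprintf("<img src='%s' alt='PCA'/>", fig_data_uri(p))
  }
  parts <- c(parts, section("Dimension reduction", pca_body))

  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<title>single-cell preprocessing QC report</title><style>",
    "body{font-family:sans-serif;margin:2em;max-width:60em}",
    "table{border-collapse:collapse;margin:0.6em 0}",
    "td,th{border:1px solid #ccc;padding:0.25em 0.6em;",
    "font-size:0.85em}",
    "h1{color:#234}h2{color:#345;border-bottom:1px solid #ccc}",
    ".note{color:#a40;font-style:italic}",
    "img{max-width:100%}",
    "</style></head><body>",
    "<h1>Single-cell preprocessing QC report</h1>",
    paste(parts, collapse = "\n"),
    "</body></html>")
  writeLines(html, report_file)
  invisible(report_file)
}
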