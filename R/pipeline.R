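# End-to-end orchestration: one validated configuration drives all
# stages, each stage remains individually re-runnable, and every
# invocation is recorded in the run manifest.

#' Assemble and validate a pipeline configuration
#'
#' A configuration bundles everything a full run needs: the read
#' structure, filter settings, input paths, barcode source (a
#' whitelist file or detection parameters), counting and QC
#' parameters, the output directory and the seed. Configurations can
#' also be loaded from a YAML file with the same field names
#' ([read_pipeline_config()]). Validation happens before any stage
#' runs.
#'
#' @param out_dir run output directory.
#' @param bam coordinate-sorted BAM of transcript reads from any
#'   aligner (read names must carry the reformatted header; see
#'   [reformat_fastq()]).
#' @param r1,r2 raw FASTQ paths; optional (`NULL` starts the run at
#'   the BAM, e.g. for BAM files produced by external droplet
#'   pipelines).
#' @param annotation GTF/GFF3 annotation path.
#' @param whitelist barcode whitelist path, or `NULL` to detect
#'   barcodes from the data.
#' @param structure a [read_structure()].
#' @param filters a [reformat_filters()].
#' @param detect_mode,detect_n barcode detection settings used when
#'   `whitelist` is `NULL` (see [detect_barcodes()]).
#' @param max_mismatch barcode matching tolerance.
#' @param has_umi protocol carries UMIs?
#' @param max_hamming UMI fold distance.
#' @param bin_width feature-index bin width.
#' @param comp,conf outlier-detection settings ([detect_outliers()]).
#' @param seed integer seed recorded in the manifest and used for the
#'   QC stage.
#' @return A validated object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, bam, r1 = NULL, r2 = NULL,
                            annotation, whitelist = NULL,
                            structure = read_structure(),
                            filters = reformat_filters(),
                            detect_mode = "top_n", detect_n = 100L,
                            max_mismatch = 1L, has_umi = TRUE,
                            max_hamming = 1L, bin_width = 10000L,
                            comp = 1L, conf = 0.99, seed = 1L) {
  cfg <- list(out_dir = out_dir, bam = bam, r1 = r1, r2 = r2,
              annotation = annotation, whitelist = whitelist,
              structure = structure, filters = filters,
              detect_mode = detect_mode,
              detect_n = as.integer(detect_n),
              max_mismatch = as.integer(max_mismatch),
              has_umi = isTRUE(has_umi),
              max_hamming = as.integer(max_hamming),
              bin_width = as.integer(bin_width),
              comp = as.integer(comp), conf = conf,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_read_structure(cfg$structure)
  for (p in c("bam", "annotation")) {
    if (!file.exists(cfg[[p]])) {
      stop("configured ", p, " does not exist: ", cfg[[p]],
           call. = FALSE)
    }
  }
  if (!is.null(cfg$r1) && !file.exists(cfg$r1)) {
    stop("configured r1 does not exist: ", cfg$r1, call. = FALSE)
  }
  if (!is.null(cfg$whitelist) && !file.exists(cfg$whitelist)) {
    stop("configured whitelist does not exist: ", cfg$whitelist,
         call. = FALSE)
  }
  stopifnot(cfg$comp >= 1L, cfg$conf > 0, cfg$conf < 1,
            cfg$max_mismatch >= 0L, cfg$max_hamming >= 0L,
            cfg$bin_width >= 1L)
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  str_fields <- intersect(names(y$structure),
                          names(formals(read_structure)))
  flt_fields <- intersect(names(y$filters),
                          names(formals(reformat_filters)))
  y$structure <- do.call(read_structure, y$structure[str_fields])
  y$filters <- do.call(reformat_filters,
                       if (length(flt_fields))
                         y$filters[flt_fields] else list())
  do.call(pipeline_config,
          y[intersect(names(y), names(formals(pipeline_config)))])
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the preprocessing pipeline end to end
#'
#' Executes, in order: FASTQ reformatting (skipped when no FASTQ is
#' configured -- the run then starts from the externally produced
#' BAM), feature-index construction and BAM tagging, barcode
#' detection (when no whitelist is given), per-cell demultiplexing,
#' UMI deduplication and gene counting, QC metric aggregation,
#' outlier detection, and the HTML report. Every stage writes its
#' outputs into the run directory and appends to the run manifest, so
#' any stage can be re-run individually from its inputs. A stage
#' failure stops the run with the stage named; outputs of completed
#' stages are retained.
#'
#' @param config a [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the main results: `reformat_stats`,
#'   `mapping_stats`, `demux`, `counts`, `qc`, `outliers` and
#'   `report` (path).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()

  if (!is.null(config$r1)) {
    res$reformat_stats <- run_stage("trim-barcode", {
      s <- reformat_fastq(config$r1, config$r2,
                          file.path(out_dir, "transcript.fastq.gz"),
                          config$structure, config$filters)
      write_stats_csv(s, file.path(out_dir, "reformat_stats.csv"))
      append_manifest(out_dir, "trim-barcode",
                      params = c(unclass(config$structure),
                                 unclass(config$filters)),
                      inputs = c(config$r1, config$r2),
                      outputs = "transcript.fastq.gz")
      pipeline_log("trim-barcode", "%d/%d read pairs kept",
                   s$kept, s$total_read_pairs)
      s
    })
  } else {
    pipeline_log("trim-barcode", "no FASTQ configured; starting from BAM")
  }

  index <- run_stage("exon-map", {
    build_feature_index(config$annotation,
                        bin_width = config$bin_width)
  })
  res$mapping_stats <- run_stage("exon-map", {
    s <- tag_bam(config$bam, index,
                 file.path(out_dir, "tagged.bam"))
    write_stats_csv(s, file.path(out_dir, "mapping_stats.csv"))
    append_manifest(out_dir, "exon-map",
                    params = list(bin_width = config$bin_width),
                    inputs = c(config$bam, config$annotation),
                    outputs = "tagged.bam")
    pipeline_log("exon-map", "%d exon, %d ercc, %d intron reads",
                 s$exon, s$ercc, s$intron)
    s
  })

  wl <- run_stage("detect-bc", {
    if (!is.null(config$whitelist)) {
      read_whitelist(config$whitelist)
    } else {
      bc <- read_tagged_bam(file.path(out_dir, "tagged.bam"))$barcode
      w <- detect_barcodes(bc, mode = config$detect_mode,
                           n_or_cutoff = config$detect_n)
      write_whitelist(w, file.path(out_dir, "detected_barcodes.txt"))
      append_manifest(out_dir, "detect-bc",
                      params = list(mode = config$detect_mode,
                                    n_or_cutoff = config$detect_n),
                      outputs = "detected_barcodes.txt")
      pipeline_log("detect-bc", "%d barcodes detected", nrow(w))
      w
    }
  })

  res$demux <- run_stage("demultiplex", {
    d <- demultiplex(file.path(out_dir, "tagged.bam"), wl, out_dir,
                     max_mismatch = config$max_mismatch,
                     has_umi = config$has_umi)
    append_manifest(out_dir, "demultiplex",
                    params = list(max_mismatch = config$max_mismatch,
                                  has_umi = config$has_umi),
                    inputs = "tagged.bam", outputs = "cells/")
    pipeline_log("demultiplex",
                 "%d exact, %d mismatch, %d unmatched, %d ambiguous",
                 d$stats$exact_match, d$stats$mismatch_match,
                 d$stats$unmatched, d$stats$ambiguous)
    d
  })

  res$counts <- run_stage("count", {
    cnt <- count_genes(out_dir, index_gene_ids(index),
                       has_umi = config$has_umi,
                       max_hamming = config$max_hamming,
                       out_dir = out_dir)
    append_manifest(out_dir, "count",
                    params = list(has_umi = config$has_umi,
                                  max_hamming = config$max_hamming),
                    outputs = c("gene_count.csv", "gene_count.mtx"))
    pipeline_log("count", "%d genes x %d cells, %d molecules",
                 nrow(cnt$matrix), ncol(cnt$matrix),
                 sum(cnt$matrix))
    cnt
  })

  res$qc <- run_stage("qc", {
    qc <- compute_qc_table(res$demux$cell_stats,
                           res$counts$dedup_stats,
                           res$counts$matrix, index)
    utils::write.csv(qc, file.path(out_dir, "qc_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    qc
  })
  res$outliers <- run_stage("qc", {
    oc <- detect_outliers(res$qc, comp = config$comp,
                          conf = config$conf, seed = config$seed)
    utils::write.csv(oc, file.path(out_dir, "outliers.csv"),
                     row.names = FALSE, quote = FALSE)
    append_manifest(out_dir, "qc",
                    params = list(comp = config$comp,
                                  conf = config$conf,
                                  seed = config$seed),
                    outputs = c("qc_metrics.csv", "outliers.csv"))
    pipeline_log("qc", "%d/%d cells flagged as outliers",
                 sum(oc$is_outlier), nrow(oc))
    oc
  })

  res$report <- run_stage("report", {
    r <- create_report(out_dir)
    append_manifest(out_dir, "report", outputs = "report.html")
    r
  })
  pipeline_log("run", "complete: %s", out_dir)
  invisible(res)
}
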