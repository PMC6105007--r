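# Molecule counting: greedy hamming-distance UMI deduplication per
# (cell, gene), gene count matrix assembly, and raw UMI export for
# external correction methods.

#' Deduplicate a set of UMIs with the greedy hamming rule
#'
#' Collapses sequencing-error UMI variants within one (cell, gene)
#' pair. UMIs are processed in descending read-count order (ties
#' broken lexicographically); a UMI is folded into an already-retained
#' UMI when the two are within `max_hamming` of each other **and** the
#' retained UMI has more than twice the read count of the candidate
#' (strictly, so an exactly-double count does not merge). The rule
#' reflects the observation that erroneous UMI sequences typically
#' carry only one or two reads. Counts are frozen at their input
#' values during the pass and folds only target retained UMIs, so no
#' chains (A into B into C) can form. When several retained UMIs
#' qualify, the fold targets the closest one, then the most abundant,
#' then the lexicographically smallest.
#'
#' @param umis named integer vector: UMI sequence -> read count.
#' @param max_hamming maximum hamming distance for a fold (default 1).
#' @return A list with `molecules` (number of retained UMIs),
#'   `retained` (named counts after folding) and `merge_map` (a
#'   data.frame `from`, `into`, `count` with one row per input UMI;
#'   retained UMIs map to themselves).
#' @examples
#' dedup_umis(c(AAAA = 10L, AAAT = 3L))$molecules  # 1: folded
#' dedup_umis(c(AAAA = 4L, AAAT = 3L))$molecules   # 2: 4 <= 2 * 3
#' @export
dedup_umis <- function(umis, max_hamming = 1L) {
  stopifnot(length(umis) >= 1L, all(umis >= 1L))
  seqs <- names(umis)
  if (is.null(seqs) || any(seqs == "")) {
    stop("umis must be a named vector (UMI sequence -> count)",
         call. = FALSE)
  }
  if (length(unique(nchar(seqs))) > 1L) {
    stop("UMIs of mixed lengths within one gene", call. = FALSE)
  }
  counts <- as.integer(umis)
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]
  counts <- counts[ord]
  n <- length(seqs)
  len <- nchar(seqs[1L])
  mat <- seq_byte_matrix(seqs, len)

  into <- integer(n)       # index of the UMI each input folds into
  retained <- integer(0)
  ret_counts <- integer(0)
  for (i in seq_len(n)) {
    target <- 0L
    if (length(retained) && max_hamming > 0L) {
      d <- colSums(t(mat[retained, , drop = FALSE]) != mat[i, ])
      ok <- which(d <= max_hamming & ret_counts > 2L * counts[i])
      if (length(ok)) {
        # nearest, then most abundant, then lexicographically first;
        # `retained` is already in (count desc, lex) order
        target <- retained[ok[which.min(d[ok])]]
      }
    }
    if (target == 0L) {
      retained <- c(retained, i)
      ret_counts <- c(ret_counts, counts[i])
      into[i] <- i
    } else {
      into[i] <- target
    }
  }
  folded <- tapply(counts, factor(into, levels = retained), sum)
  list(
    molecules = length(retained),
    retained = stats::setNames(as.integer(folded), seqs[retained]),
    merge_map = data.frame(from = seqs, into = seqs[into],
                           count = counts, stringsAsFactors = FALSE)
  )
}

new_dedup_stats <- function(cell_ids) {
  data.frame(cell_id = cell_ids, reads_in = 0L, distinct_umis = 0L,
             molecules_out = 0L, umis_corrected = 0L,
             stringsAsFactors = FALSE)
}

#' Build the gene count matrix from per-cell read tables
#'
#' Reads the per-cell tables written by [demultiplex()] and produces a
#' genes-by-cells matrix of molecule counts. In UMI mode each entry is
#' the number of retained UMIs after [dedup_umis()]; in non-UMI mode
#' (`has_umi = FALSE`) each entry is the read count. The raw
#' (pre-deduplication) UMI multiset of every (cell, gene) pair is
#' exported alongside the matrix so that external, more sophisticated
#' UMI-correction methods can be applied when PCR error rates are
#' high.
#'
#' @param demux_dir directory written by [demultiplex()] (must contain
#'   `cell_manifest.csv` and `cells/`).
#' @param gene_ids complete vector of annotated gene (and spike-in)
#'   ids; a table referencing an unknown id is an error, since it
#'   indicates an annotation/table mismatch. See [index_gene_ids()].
#' @param has_umi deduplicate UMIs (`TRUE`) or count reads (`FALSE`)?
#' @param max_hamming fold distance for [dedup_umis()].
#' @param out_dir if non-`NULL`, the matrix is written there as
#'   `gene_count.csv` and MatrixMarket (`gene_count.mtx` +
#'   `gene_count_rownames.txt` / `_colnames.txt`), the per-cell
#'   deduplication statistics as `dedup_stats.csv`, and the raw UMI
#'   export as `raw_umi.csv` (columns cell_id, gene_id, umi, reads).
#' @return A list with `matrix` (integer matrix, genes x cells),
#'   `dedup_stats` (per-cell data.frame with `reads_in`,
#'   `distinct_umis`, `molecules_out`, `umis_corrected`) and `raw_umi`
#'   (data.frame of raw UMI counts per cell and gene).
#' @export
count_genes <- function(demux_dir, gene_ids, has_umi = TRUE,
                        max_hamming = 1L, out_dir = NULL) {
  manifest <- utils::read.csv(
    file.path(demux_dir, "cell_manifest.csv"),
    stringsAsFactors = FALSE)
  cells <- manifest$cell_id
  mat <- matrix(0L, nrow = length(gene_ids), ncol = length(cells),
                dimnames = list(gene_ids, cells))
  dstats <- new_dedup_stats(cells)
  raw <- vector("list", length(cells))

  for (i in seq_along(cells)) {
    tab <- utils::read.csv(file.path(demux_dir, manifest$file[i]),
                           colClasses = c("character", "character",
                                          "integer"),
                           stringsAsFactors = FALSE)
    dstats$reads_in[i] <- nrow(tab)
    if (nrow(tab) == 0L) next
    unknown <- setdiff(unique(tab$gene_id), gene_ids)
    if (length(unknown)) {
      stop("per-cell table for ", cells[i], " references gene ids ",
           "absent from the annotation: ",
           paste(utils::head(unknown, 5L), collapse = ", "),
           call. = FALSE)
    }
    dt <- data.table::as.data.table(tab)
    per <- dt[, .(reads = .N), by = .(gene_id, umi)]
    raw[[i]] <- data.frame(cell_id = cells[i], per,
                           stringsAsFactors = FALSE)
    if (has_umi) {
      dstats$distinct_umis[i] <- nrow(per)
      mol <- per[, .(molecules = dedup_umis(
        stats::setNames(reads, umi), max_hamming)$molecules),
        by = gene_id]
      mat[mol$gene_id, i] <- mol$molecules
      dstats$molecules_out[i] <- sum(mol$molecules)
    } else {
      reads_per_gene <- dt[, .N, by = gene_id]
      mat[reads_per_gene$gene_id, i] <- reads_per_gene$N
      dstats$distinct_umis[i] <- nrow(per)
      dstats$molecules_out[i] <- sum(reads_per_gene$N)
    }
  }
  dstats$umis_corrected <- if (has_umi) {
    dstats$distinct_umis - dstats$molecules_out
  } else 0L
  raw <- raw[!vapply(raw, is.null, logical(1))]
  raw <- if (length(raw)) {
    do.call(rbind, c(raw, list(make.row.names = FALSE)))
  } else {
    data.frame(cell_id = character(), gene_id = character(),
               umi = character(), reads = integer())
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(mat, out_dir)
    utils::write.csv(dstats, file.path(out_dir, "dedup_stats.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(raw, file.path(out_dir, "raw_umi.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(matrix = mat, dedup_stats = dstats, raw_umi = raw)
}

#' Write / read a gene count matrix
#'
#' The matrix is serialised both as a dense CSV (genes in rows, cells
#' in columns) and as a sparse MatrixMarket file with separate row-
#' and column-name text files, the format downstream single-cell
#' toolkits ingest directly.
#'
#' @param mat integer matrix, genes x cells.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return The directory, invisibly.
#' @export
write_count_matrix <- function(mat, dir, prefix = "gene_count") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(mat),
                   file.path(dir, paste0(prefix, ".csv")),
                   row.names = TRUE, quote = FALSE)
  sp <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, paste0(prefix, ".mtx")))
  writeLines(rownames(mat),
             file.path(dir, paste0(prefix, "_rownames.txt")))
  writeLines(colnames(mat),
             file.path(dir, paste0(prefix, "_colnames.txt")))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir, prefix = "gene_count") {
  mm <- Matrix::readMM(file.path(dir, paste0(prefix, ".mtx")))
  rownames(mm) <- readLines(file.path(dir,
                                      paste0(prefix, "_rownames.txt")))
  colnames(mm) <- readLines(file.path(dir,
                                      paste0(prefix, "_colnames.txt")))
  m <- as.matrix(mm)
  storage.mode(m) <- "integer"
  m
}
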