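# Cell-barcode handling: hamming matching against a whitelist,
# detection of enriched barcodes by count-and-collapse, and per-cell
# demultiplexing of a tagged BAM.

#' Read / write a barcode whitelist
#'
#' A whitelist is a plain-text file with one barcode per line and an
#' optional second (comma- or tab-separated) column giving the cell
#' id. Missing cell ids are generated as `cell_001`, `cell_002`, ...
#' in file order.
#'
#' @param path whitelist file path.
#' @return A data.frame with columns `cell_id` and `barcode`.
#' @export
read_whitelist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\t]")
  bc <- toupper(vapply(parts, `[[`, character(1), 1L))
  id <- vapply(parts, function(p) {
    if (length(p) >= 2L) p[[2L]] else NA_character_
  }, character(1))
  if (anyNA(id)) {
    id <- ifelse(is.na(id),
                 sprintf("cell_%03d", seq_along(bc)), id)
  }
  wl <- data.frame(cell_id = id, barcode = bc,
                   stringsAsFactors = FALSE)
  validate_whitelist(wl)
  wl
}

#' @rdname read_whitelist
#' @param whitelist a data.frame with `cell_id` and `barcode` columns.
#' @export
write_whitelist <- function(whitelist, path) {
  validate_whitelist(whitelist)
  writeLines(paste(whitelist$barcode, whitelist$cell_id, sep = ","),
             path)
  invisible(path)
}

validate_whitelist <- function(wl) {
  stopifnot(is.data.frame(wl),
            all(c("cell_id", "barcode") %in% names(wl)))
  if (anyDuplicated(wl$barcode)) {
    stop("whitelist barcodes are not unique", call. = FALSE)
  }
  if (length(unique(nchar(wl$barcode))) > 1L) {
    stop("whitelist barcodes have unequal lengths", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", wl$barcode))) {
    stop("whitelist barcodes contain characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  invisible(wl)
}

# Byte matrix (n x len) of equal-length sequences, for vectorized
# hamming computations.
seq_byte_matrix <- function(x, len) {
  matrix(utf8ToInt(paste(x, collapse = "")), ncol = len, byrow = TRUE)
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b character vectors of equal-length sequences (recycled).
#' @return Integer vector of pairwise distances.
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  stopifnot(all(nchar(a) == nchar(b)))
  len <- nchar(a[1L])
  if (n == 0L) return(integer())
  stopifnot(all(nchar(a) == len))
  ma <- seq_byte_matrix(a, len)
  mb <- seq_byte_matrix(b, len)
  as.integer(rowSums(ma != mb))
}

#' Match observed barcodes against a whitelist with mismatch tolerance
#'
#' Each observed barcode is assigned to the unique whitelist entry at
#' minimal hamming distance, provided that distance is at most
#' `max_mismatch`. Exact matches short-circuit. When two or more
#' whitelist entries tie at the minimal distance the read is left
#' unassigned (category `ambiguous`) rather than assigned arbitrarily,
#' which would contaminate cells.
#'
#' @param observed character vector of observed barcode sequences, all
#'   the same length as the whitelist barcodes.
#' @param whitelist a whitelist data.frame (see [read_whitelist()]).
#' @param max_mismatch maximum hamming distance for a match.
#' @return A data.frame with one row per observed barcode: `cell_id`
#'   (`NA` when unassigned), `distance` and `category` (one of
#'   `exact_match`, `mismatch_match`, `unmatched`, `ambiguous`).
#' @export
match_barcode <- function(observed, whitelist, max_mismatch = 1L) {
  validate_whitelist(whitelist)
  len <- nchar(whitelist$barcode[1L])
  if (length(observed) && any(nchar(observed) != len)) {
    stop("observed barcode length differs from whitelist length (",
         len, "); check the read structure", call. = FALSE)
  }
  uo <- unique(observed)
  m <- length(uo)
  cell <- rep(NA_character_, m)
  dist <- rep(NA_integer_, m)
  cat <- rep("unmatched", m)

  exact <- match(uo, whitelist$barcode)
  hit <- !is.na(exact)
  cell[hit] <- whitelist$cell_id[exact[hit]]
  dist[hit] <- 0L
  cat[hit] <- "exact_match"

  todo <- which(!hit)
  if (length(todo) && max_mismatch > 0L) {
    mo <- seq_byte_matrix(uo[todo], len)
    d <- matrix(0L, nrow = length(todo), ncol = nrow(whitelist))
    for (j in seq_len(nrow(whitelist))) {
      wb <- utf8ToInt(whitelist$barcode[j])
      d[, j] <- rowSums(mo != matrix(wb, nrow = length(todo),
                                     ncol = len, byrow = TRUE))
    }
    dmin <- apply(d, 1L, min)
    nmin <- rowSums(d == dmin)
    ok <- dmin <= max_mismatch
    amb <- ok & nmin > 1L
    uniq <- ok & nmin == 1L
    best <- max.col(-d, ties.method = "first")
    cell[todo[uniq]] <- whitelist$cell_id[best[uniq]]
    dist[todo[uniq]] <- dmin[uniq]
    cat[todo[uniq]] <- "mismatch_match"
    dist[todo[amb]] <- dmin[amb]
    cat[todo[amb]] <- "ambiguous"
  }
  i <- match(observed, uo)
  data.frame(cell_id = cell[i], distance = dist[i], category = cat[i],
             stringsAsFactors = FALSE)
}

#' Detect enriched cell barcodes by counting and collapsing
#'
#' For droplet protocols (10X, Drop-seq) the cell barcodes must be
#' discovered from the data. This function counts the distinct barcode
#' sequences in (a sample of) the reads, then walks them in descending
#' count order folding any barcode within `collapse_distance` (hamming)
#' of an already-accepted, more abundant barcode into that barcode --
#' such near-duplicates are indicative of sequencing errors. The
#' result is either the top `n` barcodes (`mode = "top_n"`) or all
#' barcodes whose collapsed count reaches a cutoff
#' (`mode = "min_count"`). A deliberately relaxed selection (more
#' barcodes than expected cells) is recommended; erroneous cell
#' barcodes are removed later by the QC step rather than by read-count
#' thresholds alone.
#'
#' Counting aggregates before ranking and ties are broken
#' lexicographically, so the output is independent of read order.
#'
#' @param barcodes character vector of observed barcode sequences
#'   (e.g. from the headers of a reformatted FASTQ, see
#'   [barcodes_from_fastq()], or BC tags of a tagged BAM).
#' @param mode `"top_n"` or `"min_count"`.
#' @param n_or_cutoff number of barcodes to report, or the minimum
#'   collapsed read count.
#' @param collapse_distance hamming distance within which a less
#'   abundant barcode is folded into an accepted one.
#' @param max_reads only the first `max_reads` barcodes are counted.
#' @return A whitelist data.frame with columns `cell_id`, `barcode`
#'   and `count` (collapsed read count), ordered by decreasing count.
#' @export
detect_barcodes <- function(barcodes, mode = c("top_n", "min_count"),
                            n_or_cutoff = 100L, collapse_distance = 1L,
                            max_reads = 5000000L) {
  mode <- match.arg(mode)
  stopifnot(length(barcodes) >= 1L, collapse_distance >= 0L)
  if (length(barcodes) > max_reads) {
    barcodes <- barcodes[seq_len(max_reads)]
  }
  if (length(unique(nchar(barcodes))) > 1L) {
    stop("observed barcodes have unequal lengths", call. = FALSE)
  }
  tab <- table(barcodes)
  seqs <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]
  counts <- counts[ord]

  len <- nchar(seqs[1L])
  mat <- seq_byte_matrix(seqs, len)
  accepted <- integer(0)
  acc_counts <- integer(0)
  for (i in seq_along(seqs)) {
    folded <- FALSE
    if (length(accepted) && collapse_distance > 0L) {
      d <- colSums(t(mat[accepted, , drop = FALSE]) != mat[i, ])
      j <- which(d <= collapse_distance)
      if (length(j)) {
        # fold into the closest accepted barcode (first by rank)
        j <- j[which.min(d[j])]
        acc_counts[j] <- acc_counts[j] + counts[i]
        folded <- TRUE
      }
    }
    if (!folded) {
      accepted <- c(accepted, i)
      acc_counts <- c(acc_counts, counts[i])
    }
  }
  out <- data.frame(barcode = seqs[accepted], count = acc_counts,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$barcode), , drop = FALSE]
  if (mode == "top_n") {
    if (n_or_cutoff > nrow(out)) {
      warning("requested ", n_or_cutoff, " barcodes but only ",
              nrow(out), " distinct barcodes found; returning all",
              call. = FALSE)
    }
    out <- utils::head(out, n_or_cutoff)
  } else {
    out <- out[out$count >= n_or_cutoff, , drop = FALSE]
  }
  data.frame(cell_id = sprintf("cell_%03d", seq_len(nrow(out))),
             barcode = out$barcode, count = out$count,
             stringsAsFactors = FALSE)
}

#' Extract the observed barcode sequences from a reformatted FASTQ
#'
#' @param fastq path to a FASTQ written by [reformat_fastq()].
#' @param max_reads read at most this many records.
#' @return Character vector of barcode sequences, one per read.
#' @export
barcodes_from_fastq <- function(fastq, max_reads = 5000000L) {
  fs <- ShortRead::FastqStreamer(fastq, n = 1000000L)
  on.exit(close(fs), add = TRUE)
  out <- character(0)
  while (length(out) < max_reads &&
         length(chunk <- ShortRead::yield(fs)) > 0L) {
    ids <- as.character(ShortRead::id(chunk))
    out <- c(out, parse_read_header(ids)$barcode)
  }
  utils::head(out, max_reads)
}

new_demux_stats <- function() {
  s <- list(exact_match = 0L, mismatch_match = 0L, unmatched = 0L,
            ambiguous = 0L)
  class(s) <- "demux_stats"
  s
}

#' @export
print.demux_stats <- function(x, ...) {
  cat("demux_stats:\n")
  for (f in names(x)) cat(sprintf("  %-16s %d\n", f, x[[f]]))
  invisible(x)
}

#' @export
as.data.frame.demux_stats <- function(x, ...) {
  data.frame(metric = names(unclass(x)),
             value = unlist(x, use.names = FALSE))
}

#' Demultiplex a tagged BAM into per-cell read tables
#'
#' Matches the `BC` tag of every primary alignment in a tagged BAM
#' (see [tag_bam()]) against the whitelist and writes, for every cell,
#' a CSV in which each row is a read assigned to a gene, with columns
#' `gene_id`, `umi` and `position` (0-based leftmost aligned
#' coordinate). Only reads with status `exon` or `ercc` contribute
#' rows; all reads contribute to the barcode-match statistics and the
#' per-cell mapping-status counts.
#'
#' With `has_umi = FALSE` (Smart-seq and other non-UMI protocols) the
#' `umi` column holds the constant placeholder `"NOUMI"` and downstream
#' counting uses reads instead of molecules.
#'
#' @param bam path to a tagged BAM.
#' @param whitelist a whitelist data.frame (see [read_whitelist()],
#'   [detect_barcodes()]).
#' @param out_dir output directory; created if missing.
#' @param max_mismatch maximum hamming distance for barcode matching.
#' @param has_umi does the protocol carry UMIs?
#' @return A list with `stats` (a `demux_stats` whose four counters sum
#'   to the number of reads processed), `cell_stats` (per-cell
#'   mapping-status counts), and `manifest` (cell_id, barcode, file,
#'   n_rows). Files written: `cells/<cell_id>.csv`,
#'   `cell_manifest.csv`, `demux_stats.csv`, `cell_mapping_stats.csv`.
#' @export
demultiplex <- function(bam, whitelist, out_dir, max_mismatch = 1L,
                        has_umi = TRUE) {
  validate_whitelist(whitelist)
  rec <- read_tagged_bam(bam)
  if (anyNA(rec$barcode)) {
    stop("BAM records lack the BC tag; run tag_bam() first",
         call. = FALSE)
  }
  if (has_umi && any(rec$umi == "")) {
    stop("has_umi = TRUE but BAM records lack the OX tag",
         call. = FALSE)
  }
  dir.create(file.path(out_dir, "cells"), recursive = TRUE,
             showWarnings = FALSE)

  m <- match_barcode(rec$barcode, whitelist, max_mismatch)
  stats <- new_demux_stats()
  for (f in names(stats)) stats[[f]] <- sum(m$category == f)
  rec[, cell_id := m$cell_id]

  # per-cell mapping-status counts over matched reads
  matched <- rec[!is.na(rec$cell_id)]
  cs <- data.table::dcast(
    matched[, .N, by = .(cell_id, status)],
    cell_id ~ status, value.var = "N", fill = 0L)
  for (s in MAPPING_STATUSES) {
    if (!s %in% names(cs)) cs[, (s) := 0L]
  }
  # cells with no matched reads still get a row
  missing <- setdiff(whitelist$cell_id, cs$cell_id)
  if (length(missing)) {
    pad <- data.table::data.table(cell_id = missing)
    for (s in MAPPING_STATUSES) pad[, (s) := 0L]
    cs <- rbind(cs, pad, fill = TRUE)
  }
  data.table::setcolorder(cs, c("cell_id", MAPPING_STATUSES))
  cs <- cs[order(cs$cell_id)]

  keep <- matched[matched$status %in% c("exon", "ercc")]
  if (!has_umi) keep[, umi := "NOUMI"]
  manifest <- data.frame(
    cell_id = whitelist$cell_id,
    barcode = whitelist$barcode,
    file = file.path("cells", paste0(whitelist$cell_id, ".csv")),
    n_rows = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    ci <- manifest$cell_id[i]
    tab <- keep[keep$cell_id == ci,
                .(gene_id, umi, position = pos - 1L)]
    utils::write.csv(tab, file.path(out_dir, manifest$file[i]),
                     row.names = FALSE, quote = FALSE)
    manifest$n_rows[i] <- nrow(tab)
  }
  utils::write.csv(manifest, file.path(out_dir, "cell_manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_stats_csv(stats, file.path(out_dir, "demux_stats.csv"))
  utils::write.csv(cs, file.path(out_dir, "cell_mapping_stats.csv"),
                   row.names = FALSE, quote = FALSE)
  list(stats = stats, cell_stats = as.data.frame(cs),
       manifest = manifest)
}
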