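# FASTQ reformatting: move cell barcode and UMI bases from the reads
# into the read header, filter low-quality / low-complexity reads, and
# emit a transcript-only FASTQ ready for any external aligner.

REJECT_REASONS <- c("removed_too_short", "removed_low_quality",
                    "removed_low_complexity")

new_reformat_stats <- function(total = 0L, kept = 0L, low_quality = 0L,
                               low_complexity = 0L, too_short = 0L) {
  s <- list(total_read_pairs = as.integer(total),
            kept = as.integer(kept),
            removed_low_quality = as.integer(low_quality),
            removed_low_complexity = as.integer(low_complexity),
            removed_too_short = as.integer(too_short))
  class(s) <- "reformat_stats"
  s
}

#' @export
print.reformat_stats <- function(x, ...) {
  cat("reformat_stats:\n")
  for (f in names(x)) cat(sprintf("  %-24s %d\n", f, x[[f]]))
  invisible(x)
}

#' @export
as.data.frame.reformat_stats <- function(x, ...) {
  data.frame(metric = names(unclass(x)),
             value = unlist(x, use.names = FALSE))
}

# Vectorized core shared by reformat_read_pair() and reformat_fastq().
# All inputs are character vectors of equal length (seq2/qual2 NULL for
# single-read layouts). Returns parallel vectors: status (one of "kept"
# or a REJECT_REASONS value), and for kept reads the output name,
# sequence and quality.
reformat_chunk <- function(name, seq1, qual1, seq2, qual2,
                           structure, filters) {
  n <- length(seq1)
  single_end <- is.null(seq2)
  if (single_end && structure$transcript_read != 1L) {
    stop("single-read input but transcript_read is 2", call. = FALSE)
  }
  segs <- structure_segments(structure)
  if (single_end && any(segs$read == 2L)) {
    stop("read structure places segments on read 2 but no read 2 given",
         call. = FALSE)
  }
  status <- rep("kept", n)

  w1 <- nchar(seq1)
  w2 <- if (single_end) NULL else nchar(seq2)

  # Segment-fit check: every declared segment must lie inside its mate.
  fits <- rep(TRUE, n)
  for (i in seq_len(nrow(segs))) {
    w <- if (segs$read[i] == 1L) w1 else w2
    fits <- fits & (segs$start[i] + segs$len[i] <= w)
  }
  # For single-end layouts the transcript is the residual suffix after
  # the trimmed segments; it must be non-empty.
  tsegs <- segs[segs$read == structure$transcript_read, , drop = FALSE]
  t_from <- if (nrow(tsegs)) max(tsegs$start + tsegs$len) else 0L
  wt <- if (structure$transcript_read == 1L) w1 else w2
  fits <- fits & (wt > t_from)
  status[!fits] <- "removed_too_short"

  ok <- status == "kept"
  # Barcode / UMI extraction (only where segments fit).
  extract <- function(x, start, len) substr(x, start + 1L, start + len)
  bc <- rep("", n)
  if (structure$bc1_len > 0L) {
    bc[ok] <- extract(seq1[ok], structure$bc1_start, structure$bc1_len)
  }
  if (structure$bc2_len > 0L) {
    bc[ok] <- paste0(bc[ok], extract(seq2[ok], structure$bc2_start,
                                     structure$bc2_len))
  }
  umi <- rep("", n)
  if (structure$umi_len > 0L) {
    useq <- if (structure$umi_read == 1L) seq1 else seq2
    umi[ok] <- extract(useq[ok], structure$umi_start, structure$umi_len)
  }

  # Quality filter over the combined barcode + UMI region.
  if (any(ok) && filters$max_low_quality_bases >= 0L) {
    tagqual <- rep("", n)
    for (i in seq_len(nrow(segs))) {
      q <- if (segs$read[i] == 1L) qual1 else qual2
      tagqual[ok] <- paste0(tagqual[ok],
                            extract(q[ok], segs$start[i], segs$len[i]))
    }
    wq <- sum(segs$len)
    qmat <- matrix(utf8ToInt(paste(tagqual[ok], collapse = "")),
                   ncol = wq, byrow = TRUE)
    thr <- filters$quality_offset + filters$min_barcode_quality
    nlow <- rowSums(qmat < thr)
    bad <- which(ok)[nlow > filters$max_low_quality_bases]
    status[bad] <- "removed_low_quality"
    ok <- status == "kept"
  }

  # Transcript sequence: the non-barcode mate, or the residual suffix.
  tseq <- if (structure$transcript_read == 1L) seq1 else seq2
  tqual <- if (structure$transcript_read == 1L) qual1 else qual2
  out_seq <- rep("", n)
  out_qual <- rep("", n)
  out_seq[ok] <- substr(tseq[ok], t_from + 1L, nchar(tseq[ok]))
  out_qual[ok] <- substr(tqual[ok], t_from + 1L, nchar(tqual[ok]))

  # Complexity filter: longest mononucleotide run as a fraction of the
  # transcript length, plus an N-content guard.
  if (filters$complexity_filter && any(ok)) {
    idx <- which(ok)
    s <- out_seq[idx]
    run <- longest_base_run(s)
    frac <- run / nchar(s)
    nfrac <- nchar(gsub("[^N]", "", s)) / nchar(s)
    bad <- idx[frac > filters$max_mononucleotide_fraction | nfrac > 0.9]
    status[bad] <- "removed_low_complexity"
    ok <- status == "kept"
  }

  out_name <- rep("", n)
  out_name[ok] <- encode_read_header(bc[ok], umi[ok], name[ok])
  list(status = status, name = out_name, seq = out_seq, qual = out_qual,
       barcode = bc, umi = umi)
}

# Length of the longest single-base run in each sequence.
longest_base_run <- function(x) {
  run <- rep(1L, length(x))
  run[nchar(x) == 0L] <- 0L
  for (b in c("A", "C", "G", "T", "N")) {
    m <- gregexpr(paste0(b, "+"), x)
    run <- pmax(run, vapply(m, function(mm) {
      max(attr(mm, "match.length"))
    }, integer(1)))
  }
  run
}

#' Reformat a single read pair
#'
#' Applies the barcode/UMI trimming and filtering rules of
#' [reformat_fastq()] to one read pair. Mostly useful for inspecting
#' what happens to an individual read; whole files should go through
#' [reformat_fastq()].
#'
#' @param read1,read2 lists with elements `name`, `seq`, `qual`
#'   (`read2 = NULL` for single-read layouts).
#' @param structure a [read_structure()].
#' @param filters a [reformat_filters()].
#' @return A list with `status` (`"kept"` or a rejection reason among
#'   `"removed_too_short"`, `"removed_low_quality"`,
#'   `"removed_low_complexity"`) and, when kept, `record` (the output
#'   transcript record with barcode/UMI encoded in its name).
#' @export
reformat_read_pair <- function(read1, read2 = NULL,
                               structure = read_structure(),
                               filters = reformat_filters()) {
  stopifnot(nchar(read1$seq) == nchar(read1$qual))
  if (!is.null(read2)) stopifnot(nchar(read2$seq) == nchar(read2$qual))
  r <- reformat_chunk(read1$name, read1$seq, read1$qual,
                      read2$seq, read2$qual, structure, filters)
  if (r$status == "kept") {
    list(status = "kept",
         record = list(name = r$name, seq = r$seq, qual = r$qual))
  } else {
    list(status = r$status, record = NULL)
  }
}

#' Trim barcodes and UMIs from FASTQ files into the read header
#'
#' Streams a (pair of) FASTQ file(s), extracts the cell barcode and UMI
#' segments declared by `structure`, applies quality and complexity
#' filters, and writes a transcript-only FASTQ whose read names encode
#' barcode and UMI as `"<barcode>_<umi>#<original name>"` (see
#' [parse_read_header()]). The output can be aligned by any aligner
#' that preserves read names, after which [tag_bam()] recovers the
#' barcode and UMI into BAM tags.
#'
#' Gzipped input is auto-detected; the output is gzipped when `out`
#' ends in `.gz`. The order of kept reads follows the input order and
#' identical inputs always give identical output.
#'
#' @param r1 path to the read-1 FASTQ.
#' @param r2 path to the read-2 FASTQ, or `NULL` for single-read
#'   layouts.
#' @param out path of the output FASTQ.
#' @param structure a [read_structure()].
#' @param filters a [reformat_filters()].
#' @param yield_size reads per streamed chunk.
#' @return A `reformat_stats` object; its counters
#'   (`kept + removed_* = total_read_pairs`) always account for every
#'   input pair.
#' @export
reformat_fastq <- function(r1, r2 = NULL, out,
                           structure = read_structure(),
                           filters = reformat_filters(),
                           yield_size = 100000L) {
  stopifnot(file.exists(r1))
  if (!is.null(r2)) stopifnot(file.exists(r2))
  if (file.exists(out)) file.remove(out)

  f1 <- ShortRead::FastqStreamer(r1, n = yield_size)
  on.exit(close(f1), add = TRUE)
  f2 <- NULL
  if (!is.null(r2)) {
    f2 <- ShortRead::FastqStreamer(r2, n = yield_size)
    on.exit(close(f2), add = TRUE)
  }
  stats <- new_reformat_stats()
  compress <- grepl("\\.gz$", out)
  repeat {
    chunk1 <- ShortRead::yield(f1)
    chunk2 <- if (is.null(f2)) NULL else ShortRead::yield(f2)
    if (length(chunk1) == 0L) {
      if (!is.null(chunk2) && length(chunk2) > 0L) {
        stop("read counts differ between '", r1, "' and '", r2, "'",
             call. = FALSE)
      }
      break
    }
    if (!is.null(chunk2) && length(chunk2) != length(chunk1)) {
      stop("read counts differ between '", r1, "' and '", r2, "'",
           call. = FALSE)
    }
    r <- reformat_chunk(
      name = as.character(ShortRead::id(chunk1)),
      seq1 = as.character(ShortRead::sread(chunk1)),
      qual1 = as.character(Biostrings::quality(
        Biostrings::quality(chunk1))),
      seq2 = if (is.null(chunk2)) NULL else
        as.character(ShortRead::sread(chunk2)),
      qual2 = if (is.null(chunk2)) NULL else
        as.character(Biostrings::quality(Biostrings::quality(chunk2))),
      structure = structure, filters = filters
    )
    keep <- r$status == "kept"
    if (any(keep)) {
      rec <- ShortRead::ShortReadQ(
        sread = Biostrings::DNAStringSet(r$seq[keep]),
        quality = Biostrings::BStringSet(r$qual[keep]),
        id = Biostrings::BStringSet(r$name[keep])
      )
      ShortRead::writeFastq(rec, out, mode = "a", compress = compress)
    }
    stats$total_read_pairs <- stats$total_read_pairs + length(chunk1)
    stats$kept <- stats$kept + sum(keep)
    stats$removed_low_quality <- stats$removed_low_quality +
      sum(r$status == "removed_low_quality")
    stats$removed_low_complexity <- stats$removed_low_complexity +
      sum(r$status == "removed_low_complexity")
    stats$removed_too_short <- stats$removed_too_short +
      sum(r$status == "removed_too_short")
  }
  if (!file.exists(out)) {
    # empty input or everything filtered: still emit a valid empty file
    ShortRead::writeFastq(ShortRead::ShortReadQ(), out,
                          mode = "w", compress = compress)
  }
  stats
}

#' Write stage statistics to CSV
#'
#' Serialises a stats object (reformat, demultiplexing or UMI
#' deduplication statistics) as a two-column `metric,value` CSV, the
#' single source of truth consumed by [create_report()].
#'
#' @param stats a stats object with scalar integer fields.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
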