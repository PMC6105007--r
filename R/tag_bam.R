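# BAM tagging: recover barcode/UMI from the reformatted read names,
# assign every primary alignment a gene and mapping status, and write
# the result to standard BAM tags (BC = cell barcode, OX = UMI,
# GE = gene id, YS = mapping status).

new_mapping_stats <- function() {
  s <- as.list(stats::setNames(integer(length(MAPPING_STATUSES)),
                               MAPPING_STATUSES))
  s$secondary_skipped <- 0L
  class(s) <- "mapping_stats"
  s
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat("mapping_stats:\n")
  for (f in names(x)) cat(sprintf("  %-20s %d\n", f, x[[f]]))
  invisible(x)
}

#' @export
as.data.frame.mapping_stats <- function(x, ...) {
  data.frame(metric = names(unclass(x)),
             value = unlist(x, use.names = FALSE))
}

# Pull all primary alignments of a BAM into a data.table, including
# the fields needed to re-emit SAM records.
read_bam_records <- function(bam) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq",
             "cigar", "mrnm", "mpos", "isize", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.table::data.table(
    qname = b$qname,
    flag = b$flag,
    rname = as.character(b$rname),
    strand = as.character(b$strand),
    pos = b$pos,
    mapq = b$mapq,
    cigar = b$cigar,
    mrnm = as.character(b$mrnm),
    mpos = b$mpos,
    isize = b$isize,
    seq = as.character(b$seq),
    qual = as.character(b$qual)
  )
}

#' Assign genes to BAM alignments and write barcode/UMI/gene tags
#'
#' Reads a BAM whose read names carry the barcode/UMI header written by
#' [reformat_fastq()], classifies every primary alignment against the
#' feature index (see [assign_alignment()]) and writes a tagged BAM in
#' the input record order. Each primary alignment receives the tags
#' `BC` (cell barcode), `OX` (UMI sequence, when present), `GE` (gene
#' id, for `exon`/`ercc` reads) and `YS` (mapping status). Secondary
#' and supplementary alignments are skipped and counted separately.
#'
#' @param bam_in input BAM path (any aligner; read names must follow
#'   the `"<barcode>_<umi>#<name>"` scheme).
#' @param index a [build_feature_index()] result.
#' @param bam_out output BAM path.
#' @param min_overlap,stranded passed to the assignment rule.
#' @return A `mapping_stats` object whose per-status counts sum to the
#'   number of primary alignments processed.
#' @export
tag_bam <- function(bam_in, index, bam_out, min_overlap = 1L,
                    stranded = FALSE) {
  stopifnot(file.exists(bam_in))
  hdr <- Rsamtools::scanBamHeader(bam_in)[[1L]]
  rec <- read_bam_records(bam_in)
  stats <- new_mapping_stats()

  secondary <- bitwAnd(rec$flag, 256L) > 0L |
    bitwAnd(rec$flag, 2048L) > 0L
  stats$secondary_skipped <- sum(secondary)
  rec <- rec[!secondary]

  # hard error on unparseable names: the upstream reformatting step was
  # skipped or used a different scheme
  hdrinfo <- parse_read_header(rec$qname)
  rec[, `:=`(barcode = hdrinfo$barcode, umi = hdrinfo$umi)]

  unmapped <- bitwAnd(rec$flag, 4L) > 0L
  rec[, read_id := seq_len(.N)]
  mapped <- rec[!unmapped]
  blocks <- if (nrow(mapped)) {
    bl <- cigar_blocks(mapped$cigar, mapped$pos - 1L)
    nb <- vapply(bl, nrow, integer(1))
    data.table::data.table(
      read_id = rep(mapped$read_id, nb),
      bstart = unlist(lapply(bl, `[[`, "bstart"), use.names = FALSE),
      bend = unlist(lapply(bl, `[[`, "bend"), use.names = FALSE))
  } else {
    data.table::data.table(read_id = integer(), bstart = integer(),
                           bend = integer())
  }
  reads <- data.table::data.table(
    read_id = rec$read_id, chrom = rec$rname, strand = rec$strand,
    unmapped = unmapped)
  asg <- assign_blocks(reads, blocks, index, min_overlap, stranded)
  rec[, `:=`(status = asg$status, gene_id = asg$gene_id)]
  for (s in MAPPING_STATUSES) stats[[s]] <- sum(rec$status == s)

  write_tagged_bam(rec, hdr, bam_out)
  stats
}

# Emit records as SAM text with the BC/OX/GE/YS tags appended, then
# convert to BAM via Rsamtools.
write_tagged_bam <- function(rec, hdr, bam_out) {
  hlines <- character()
  if (!is.null(hdr$text) && length(hdr$text)) {
    hlines <- vapply(seq_along(hdr$text), function(i) {
      paste(c(names(hdr$text)[i], hdr$text[[i]]), collapse = "\t")
    }, character(1))
  }
  tags <- paste0("BC:Z:", rec$barcode)
  tags <- ifelse(rec$umi != "", paste0(tags, "\tOX:Z:", rec$umi), tags)
  tags <- ifelse(!is.na(rec$gene_id),
                 paste0(tags, "\tGE:Z:", rec$gene_id), tags)
  tags <- paste0(tags, "\tYS:Z:", rec$status)
  body <- paste(
    rec$qname, rec$flag,
    ifelse(is.na(rec$rname), "*", rec$rname),
    ifelse(is.na(rec$pos), 0L, rec$pos),
    ifelse(is.na(rec$mapq), 0L, rec$mapq),
    ifelse(is.na(rec$cigar), "*", rec$cigar),
    ifelse(is.na(rec$mrnm), "*", rec$mrnm),
    ifelse(is.na(rec$mpos), 0L, rec$mpos),
    ifelse(is.na(rec$isize), 0L, rec$isize),
    ifelse(rec$seq == "", "*", rec$seq),
    ifelse(rec$qual == "", "*", rec$qual),
    tags, sep = "\t")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(hlines, body), sam)
  Rsamtools::asBam(sam, destination = sub("\\.bam$", "", bam_out),
                   overwrite = TRUE, indexDestination = FALSE)
  invisible(bam_out)
}

# Read a tagged BAM back into a data.table (barcode, umi, gene_id,
# status, position). Used by demultiplexing and the tests.
read_tagged_bam <- function(bam) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos"),
    tag = c("BC", "OX", "GE", "YS"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(b$qname)
  tag_or <- function(t, default) {
    v <- b$tag[[t]]
    if (is.null(v)) rep(default, n) else v
  }
  data.table::data.table(
    qname = b$qname,
    flag = b$flag,
    rname = as.character(b$rname),
    pos = b$pos,
    barcode = tag_or("BC", NA_character_),
    umi = tag_or("OX", ""),
    gene_id = tag_or("GE", NA_character_),
    status = tag_or("YS", NA_character_)
  )
}
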