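#' Describe where barcode and UMI bases sit within a read pair
#'
#' A read structure records the 0-based offsets and lengths of the cell
#' barcode segment(s) and the UMI within a read pair, which mate carries
#' the UMI and which mate carries the transcript (cDNA) sequence. It
#' drives both FASTQ reformatting ([reformat_fastq()]) and downstream
#' demultiplexing. A length of `-1` marks a segment as absent.
#'
#' Common layouts:
#' * CEL-seq / MARS-seq: barcode and UMI at the start of read 1,
#'   transcript in read 2.
#' * Chromium 10X / Drop-seq: 16 bp (or 12 bp) barcode then UMI in read
#'   1, transcript in read 2.
#' * Single-read plate protocols: barcode + UMI + transcript all in one
#'   read; set `transcript_read` to the same mate and the transcript is
#'   taken as the residual suffix after the trimmed segments.
#'
#' @param bc1_start,bc1_len 0-based offset and length of the barcode
#'   segment in read 1 (`bc1_len = -1` if absent).
#' @param bc2_start,bc2_len barcode segment in read 2 (`-1` if absent).
#' @param umi_start,umi_len UMI segment within `umi_read` (`umi_len = -1`
#'   for non-UMI protocols).
#' @param umi_read which mate (1 or 2) carries the UMI.
#' @param transcript_read which mate carries the transcript sequence.
#' @return An object of class `"read_structure"`.
#' @examples
#' # 8 bp barcode then 6 bp UMI at the start of read 1, cDNA in read 2
#' read_structure(bc1_start = 0, bc1_len = 8, umi_start = 8, umi_len = 6)
#' @export
read_structure <- function(bc1_start = 0L, bc1_len = 8L,
                           bc2_start = 0L, bc2_len = -1L,
                           umi_start = 8L, umi_len = 6L,
                           umi_read = 1L, transcript_read = 2L) {
  s <- list(
    bc1_start = as.integer(bc1_start), bc1_len = as.integer(bc1_len),
    bc2_start = as.integer(bc2_start), bc2_len = as.integer(bc2_len),
    umi_start = as.integer(umi_start), umi_len = as.integer(umi_len),
    umi_read = as.integer(umi_read),
    transcript_read = as.integer(transcript_read)
  )
  class(s) <- "read_structure"
  validate_read_structure(s)
  s
}

validate_read_structure <- function(s) {
  stopifnot(inherits(s, "read_structure"))
  if (!s$umi_read %in% c(1L, 2L)) {
    stop("umi_read must be 1 or 2", call. = FALSE)
  }
  if (!s$transcript_read %in% c(1L, 2L)) {
    stop("transcript_read must be 1 or 2", call. = FALSE)
  }
  segs <- structure_segments(s)
  for (mate in c(1L, 2L)) {
    m <- segs[segs$read == mate, , drop = FALSE]
    if (nrow(m) > 1L) {
      m <- m[order(m$start), , drop = FALSE]
      if (any(m$start[-1L] < (m$start + m$len)[-nrow(m)])) {
        stop("barcode/UMI segments overlap within read ", mate,
             call. = FALSE)
      }
    }
  }
  if (s$bc1_len <= 0L && s$bc2_len <= 0L) {
    stop("at least one barcode segment must be present", call. = FALSE)
  }
  invisible(s)
}

# data.frame of present segments: read, start, len, what
structure_segments <- function(s) {
  out <- data.frame(
    read = c(1L, 2L, s$umi_read),
    start = c(s$bc1_start, s$bc2_start, s$umi_start),
    len = c(s$bc1_len, s$bc2_len, s$umi_len),
    what = c("bc1", "bc2", "umi"),
    stringsAsFactors = FALSE
  )
  out[out$len > 0L, , drop = FALSE]
}

#' @export
print.read_structure <- function(x, ...) {
  cat("read_structure:\n")
  segs <- structure_segments(x)
  for (i in seq_len(nrow(segs))) {
    cat(sprintf("  %-3s read %d [%d, %d)\n", segs$what[i], segs$read[i],
                segs$start[i], segs$start[i] + segs$len[i]))
  }
  cat(sprintf("  transcript: read %d\n", x$transcript_read))
  invisible(x)
}

#' Filtering options applied while reformatting reads
#'
#' Controls the two optional read filters applied by [reformat_fastq()]:
#' a base-quality filter on the barcode/UMI region and a sequence
#' complexity filter on the transcript.
#'
#' @param min_barcode_quality minimum Phred score a barcode/UMI base must
#'   reach to count as high quality.
#' @param max_low_quality_bases maximum number of barcode/UMI bases
#'   allowed below `min_barcode_quality` before the read pair is
#'   rejected.
#' @param complexity_filter logical; reject low-complexity transcript
#'   reads (e.g. polyA runs)?
#' @param max_mononucleotide_fraction reject a transcript whose longest
#'   single-base run exceeds this fraction of its length. Transcripts
#'   that are more than 90% `N` are always rejected when the filter is
#'   on.
#' @param quality_offset ASCII offset of the Phred encoding (33 for
#'   modern Illumina data).
#' @return An object of class `"reformat_filters"`.
#' @export
reformat_filters <- function(min_barcode_quality = 20L,
                             max_low_quality_bases = 1L,
                             complexity_filter = TRUE,
                             max_mononucleotide_fraction = 0.9,
                             quality_offset = 33L) {
  stopifnot(min_barcode_quality >= 0,
            max_low_quality_bases >= 0,
            max_mononucleotide_fraction >= 0,
            max_mononucleotide_fraction <= 1)
  f <- list(
    min_barcode_quality = as.integer(min_barcode_quality),
    max_low_quality_bases = as.integer(max_low_quality_bases),
    complexity_filter = isTRUE(complexity_filter),
    max_mononucleotide_fraction = as.numeric(max_mononucleotide_fraction),
    quality_offset = as.integer(quality_offset)
  )
  class(f) <- "reformat_filters"
  f
}

# Reserved separators of the read-header encoding:
# "<barcode>_<umi>#<original name>". Barcode and UMI never contain "_"
# or "#" (DNA alphabet), so parsing is unambiguous.
HEADER_SEP_BC_UMI <- "_"
HEADER_SEP_NAME <- "#"

#' Encode / decode barcode and UMI in a read name
#'
#' Reformatted reads carry their cell barcode and UMI in the read name
#' as `"<barcode>_<umi>#<original name>"`. Aligners preserve read names,
#' so this information survives alignment and is recovered when tagging
#' the BAM. For non-UMI protocols the UMI field is the empty string.
#'
#' @param barcode,umi,name character vectors (recycled).
#' @return `encode_read_header()` returns a character vector of encoded
#'   names; `parse_read_header()` returns a data.frame with columns
#'   `barcode`, `umi` and `name`.
#' @examples
#' h <- encode_read_header("ACGTACGT", "AAATTT", "read1")
#' parse_read_header(h)
#' @export
encode_read_header <- function(barcode, umi, name) {
  paste0(barcode, HEADER_SEP_BC_UMI, umi, HEADER_SEP_NAME, name)
}

#' @rdname encode_read_header
#' @export
parse_read_header <- function(name) {
  hash <- regexpr(HEADER_SEP_NAME, name, fixed = TRUE)
  if (any(hash < 0L)) {
    bad <- which(hash < 0L)[1L]
    stop("read name not in '<barcode>_<umi>#<name>' form: ", name[bad],
         call. = FALSE)
  }
  prefix <- substr(name, 1L, hash - 1L)
  rest <- substr(name, hash + 1L, nchar(name))
  us <- regexpr(HEADER_SEP_BC_UMI, prefix, fixed = TRUE)
  if (any(us < 0L)) {
    bad <- which(us < 0L)[1L]
    stop("read name not in '<barcode>_<umi>#<name>' form: ", name[bad],
         call. = FALSE)
  }
  data.frame(
    barcode = substr(prefix, 1L, us - 1L),
    umi = substr(prefix, us + 1L, nchar(prefix)),
    name = rest,
    stringsAsFactors = FALSE
  )
}
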