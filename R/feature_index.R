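# Binned interval index over gene annotation. Chromosomes are divided
# into non-overlapping fixed-width bins and each bin lists the exon and
# gene-body intervals overlapping it, so that assigning an aligned
# fragment only requires scanning the bins its blocks touch (the same
# search-reduction strategy featureCounts uses). All internal
# coordinates are 0-based half-open; GTF/GFF (1-based inclusive) is
# converted at parse time.

#' Build a binned exon/gene interval index from annotation
#'
#' Parses a GTF/GFF3 gene annotation (or takes a ready `GRanges`),
#' merges overlapping exons within each gene, derives gene bodies, and
#' distributes the intervals over fixed-width chromosome bins. The
#' resulting index drives [assign_alignment()] and [tag_bam()].
#'
#' Reference names starting with `ercc_prefix` are treated as spike-in
#' control contigs: alignments to them are classified `ercc` with the
#' contig name as gene id. Genes located on a contig named in
#' `mito_names` are recorded as mitochondrial for later QC.
#'
#' @param annotation path to a GTF or GFF3 file, or a
#'   `GenomicRanges::GRanges` with a `type` column (rows with
#'   `type == "exon"`) and a `gene_id` metadata column.
#' @param bin_width bin width in bases. Results are independent of the
#'   bin width; it only trades memory against lookup speed.
#' @param ercc_prefix reference-name prefix identifying spike-in
#'   control contigs.
#' @param mito_names reference names treated as the mitochondrial
#'   genome.
#' @return An object of class `"feature_index"`.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1";',
#'   'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1";'
#' ), gtf)
#' idx <- build_feature_index(gtf, bin_width = 1000)
#' @export
build_feature_index <- function(annotation, bin_width = 10000L,
                                ercc_prefix = "ERCC-",
                                mito_names = c("MT", "chrM", "chrMT")) {
  stopifnot(bin_width >= 1L)
  bin_width <- as.integer(bin_width)
  if (is.character(annotation)) {
    gr <- rtracklayer::import(annotation)
  } else if (methods::is(annotation, "GRanges")) {
    gr <- annotation
  } else {
    stop("annotation must be a file path or a GRanges", call. = FALSE)
  }
  if (!"type" %in% names(S4Vectors::mcols(gr))) {
    stop("annotation has no 'type' column", call. = FALSE)
  }
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon records",
                             call. = FALSE)
  gid <- S4Vectors::mcols(ex)$gene_id
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    bad <- if (is.null(gid)) 1L else which(is.na(gid) | gid == "")[1L]
    stop("exon record ", bad, " lacks a gene_id attribute",
         call. = FALSE)
  }
  gname <- S4Vectors::mcols(ex)$gene_name
  name_map <- if (!is.null(gname)) {
    m <- !is.na(gname) & !duplicated(gid)
    stats::setNames(as.character(gname[m]), gid[m])
  } else NULL

  # merge overlapping exons within each gene; derive gene bodies
  byg <- GenomicRanges::split(ex, gid)
  exm <- GenomicRanges::reduce(byg)
  bodies <- unlist(range(exm))
  exu <- unlist(exm)

  to_dt <- function(g) {
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(g)),
      # 0-based half-open
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      gene_id = names(g)
    )
  }
  exon_dt <- to_dt(exu)
  exon_dt[, exon_uid := seq_len(.N)]
  gene_dt <- to_dt(bodies)

  # replicate each interval into every bin it overlaps
  bin_expand <- function(dt) {
    first <- dt$start %/% bin_width
    nb <- (dt$end - 1L) %/% bin_width - first + 1L
    out <- dt[rep(seq_len(nrow(dt)), nb)]
    out[, bin := sequence(nb) - 1L + rep(first, nb)]
    data.table::setkeyv(out, c("chrom", "bin"))
    out
  }
  exon_bins <- bin_expand(exon_dt)
  gene_bins <- bin_expand(gene_dt)

  genes <- gene_dt[, .(chrom, start, end, strand, gene_id)]
  genes[, gene_name := if (is.null(name_map)) NA_character_ else
    unname(name_map[gene_id])]
  ercc_ids <- sort(unique(c(
    as.character(GenomeInfoDb::seqlevels(gr))[
      startsWith(as.character(GenomeInfoDb::seqlevels(gr)),
                 ercc_prefix)],
    genes$gene_id[startsWith(genes$chrom, ercc_prefix)]
  )))

  idx <- list(
    exon_bins = exon_bins,
    gene_bins = gene_bins,
    genes = genes,
    bin_width = bin_width,
    ercc_prefix = ercc_prefix,
    ercc_ids = ercc_ids,
    mito_names = mito_names,
    mito_genes = genes$gene_id[genes$chrom %in% mito_names]
  )
  class(idx) <- "feature_index"
  idx
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf(
    "feature_index: %d genes, %d merged exons, bin width %d\n",
    nrow(x$genes), max(x$exon_bins$exon_uid), x$bin_width))
  cat(sprintf("  spike-in species: %d; mitochondrial genes: %d\n",
              length(x$ercc_ids), length(x$mito_genes)))
  invisible(x)
}

#' Gene identifiers covered by a feature index
#'
#' @param index a [build_feature_index()] result.
#' @param include_ercc include spike-in control species?
#' @return Character vector of gene (and optionally spike-in) ids.
#' @export
index_gene_ids <- function(index, include_ercc = TRUE) {
  ids <- sort(index$genes$gene_id)
  if (include_ercc) ids <- c(ids, setdiff(index$ercc_ids, ids))
  ids
}

MAPPING_STATUSES <- c("exon", "intron", "ambiguous", "aligned_elsewhere",
                      "unaligned", "ercc")

# Vectorized assignment. `reads`: data.table(read_id, chrom, strand,
# unmapped); `blocks`: data.table(read_id, bstart, bend) with 0-based
# half-open aligned blocks (CIGAR M/=/X) for mapped reads. Returns a
# data.table(read_id, status, gene_id) in read_id order.
assign_blocks <- function(reads, blocks, index, min_overlap = 1L,
                          stranded = FALSE) {
  res <- data.table::data.table(
    read_id = reads$read_id,
    status = rep(NA_character_, nrow(reads)),
    gene_id = rep(NA_character_, nrow(reads))
  )
  res[reads$unmapped, status := "unaligned"]
  is_ercc <- !reads$unmapped & startsWith(reads$chrom, index$ercc_prefix)
  res[is_ercc, `:=`(status = "ercc", gene_id = reads$chrom[is_ercc])]

  known <- unique(c(index$exon_bins$chrom, index$gene_bins$chrom))
  open <- is.na(res$status)
  unknown <- open & !reads$chrom %in% known
  if (any(unknown)) {
    res[unknown, status := "aligned_elsewhere"]
    warning(sum(unknown), " alignment(s) on reference(s) absent from ",
            "the annotation counted as aligned_elsewhere",
            call. = FALSE)
  }
  open_ids <- res$read_id[is.na(res$status)]
  bl <- blocks[blocks$read_id %in% open_ids]
  if (nrow(bl)) {
    bl <- data.table::copy(bl)
    bl[, block_id := seq_len(.N)]
    bl[, chrom := reads$chrom[match(read_id, reads$read_id)]]
    if (stranded) {
      bl[, rstrand := reads$strand[match(read_id, reads$read_id)]]
    }
    bw <- index$bin_width
    first <- bl$bstart %/% bw
    nb <- (bl$bend - 1L) %/% bw - first + 1L
    expand <- bl[rep(seq_len(nrow(bl)), nb)]
    expand[, bin := sequence(nb) - 1L + rep(first, nb)]

    overlap_hits <- function(bins_dt) {
      hits <- bins_dt[expand,
                      on = c("chrom", "bin"),
                      allow.cartesian = TRUE, nomatch = NULL]
      hits <- hits[, ov := pmin(bend, end) - pmax(bstart, start)][ov > 0L]
      if (stranded && nrow(hits)) {
        hits <- hits[strand == "*" | rstrand == "*" | strand == rstrand]
      }
      hits
    }

    eh <- overlap_hits(index$exon_bins)
    if (nrow(eh)) {
      # the same exon block pair can be seen through several bins
      eh <- unique(eh, by = c("block_id", "exon_uid"))
      per_gene <- eh[, .(ov = sum(ov)), by = .(read_id, gene_id)]
      per_gene <- per_gene[ov >= min_overlap]
      ng <- per_gene[, .(n = .N, gene = gene_id[1L]), by = read_id]
      one <- ng[ng$n == 1L]
      res[match(one$read_id, res$read_id),
          `:=`(status = "exon", gene_id = one$gene)]
      res[match(ng[ng$n > 1L]$read_id, res$read_id),
          status := "ambiguous"]
    }
    still <- res$read_id[is.na(res$status)]
    gh <- overlap_hits(index$gene_bins)
    gh <- gh[gh$read_id %in% still]
    if (nrow(gh)) {
      gh <- unique(gh, by = c("block_id", "gene_id"))
      per_gene <- gh[, .(ov = sum(ov)), by = .(read_id, gene_id)]
      per_gene <- per_gene[per_gene$ov >= min_overlap]
      res[match(unique(per_gene$read_id), res$read_id),
          status := "intron"]
    }
  }
  res[is.na(status), status := "aligned_elsewhere"]
  res
}

#' Classify a single alignment against the feature index
#'
#' Assigns one aligned (or unmapped) record a mapping status among
#' `exon`, `intron`, `ambiguous`, `aligned_elsewhere`, `unaligned` and
#' `ercc`, with precedence `ercc > exon > ambiguous > intron >
#' aligned_elsewhere`. Overlap is counted over the aligned reference
#' blocks (CIGAR `M`/`=`/`X`), so spliced alignments are handled; a
#' read overlapping exons of exactly one gene by at least
#' `min_overlap` becomes `exon`, exons of several genes `ambiguous`,
#' a gene body without exon overlap `intron`.
#'
#' @param chrom reference name (ignored when `unmapped`).
#' @param pos 0-based leftmost aligned position.
#' @param cigar CIGAR string.
#' @param index a [build_feature_index()] result.
#' @param unmapped logical; is the record unmapped?
#' @param strand alignment strand (`"+"`, `"-"`, `"*"`).
#' @param min_overlap minimum exon/gene-body overlap in bases.
#' @param stranded restrict exon hits to the matching strand?
#' @return A list with `status`, `gene_id` (only for `exon`/`ercc`)
#'   and `position`.
#' @export
assign_alignment <- function(chrom, pos, cigar, index,
                             unmapped = FALSE, strand = "*",
                             min_overlap = 1L, stranded = FALSE) {
  reads <- data.table::data.table(
    read_id = 1L, chrom = as.character(chrom),
    strand = as.character(strand), unmapped = isTRUE(unmapped)
  )
  blocks <- data.table::data.table(read_id = integer(),
                                   bstart = integer(), bend = integer())
  if (!isTRUE(unmapped)) {
    rg <- cigar_blocks(cigar, as.integer(pos))[[1L]]
    blocks <- data.table::data.table(
      read_id = rep(1L, nrow(rg)), bstart = rg$bstart, bend = rg$bend)
  }
  r <- assign_blocks(reads, blocks, index, min_overlap, stranded)
  list(status = r$status[1L],
       gene_id = if (is.na(r$gene_id[1L])) NULL else r$gene_id[1L],
       position = if (isTRUE(unmapped)) NA_integer_ else as.integer(pos))
}

# Aligned reference blocks (M/=/X) from CIGAR strings; pos0 is 0-based.
# Returns a list of data.frames (bstart, bend), 0-based half-open.
cigar_blocks <- function(cigar, pos0) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos0 + 1L, ops = c("M", "=", "X"),
    reduce.ranges = TRUE)
  lapply(seq_along(rl), function(i) {
    r <- rl[[i]]
    data.frame(bstart = IRanges::start(r) - 1L,
               bend = IRanges::end(r))
  })
}
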