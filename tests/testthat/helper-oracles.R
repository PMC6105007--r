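# Independent oracles used to cross-check the implementation. These
# deliberately use naive algorithms (full scans, fixed-point loops) and
# share no code with the package internals they verify.

# Brute-force UMI deduplication: repeatedly scan UMIs in descending
# count order (ties lexicographic) and fold any still-retained UMI into
# another retained UMI within max_hamming whose frozen count is more
# than twice its own, until no fold applies. Returns the molecule count.
oracle_dedup <- function(umis, max_hamming = 1L) {
  seqs <- names(umis)
  counts <- as.integer(umis)
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]
  counts <- counts[ord]
  chars <- strsplit(seqs, "")
  parent <- seq_along(seqs)
  repeat {
    changed <- FALSE
    for (i in seq_along(seqs)) {
      if (parent[i] != i) next
      for (j in seq_along(seqs)) {
        if (j == i || parent[j] != j) next
        d <- sum(chars[[i]] != chars[[j]])
        if (d <= max_hamming && counts[j] > 2L * counts[i]) {
          parent[i] <- j
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  sum(parent == seq_along(seqs))
}

# random UMI count sets for the dedup equivalence property
random_umi_set <- function(len = 6L, max_distinct = 8L,
                           max_count = 50L) {
  k <- sample.int(max_distinct, 1L)
  seqs <- character(0)
  while (length(seqs) < k) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    # bias towards near-duplicates so folds actually trigger
    if (length(seqs) && stats::runif(1) < 0.5) {
      p <- sample.int(len, 1L)
      b <- sample(c("A", "C", "G", "T"), 1L)
      s <- paste0(substr(seqs[1L], 1L, p - 1L), b,
                  substr(seqs[1L], p + 1L, len))
    }
    seqs <- unique(c(seqs, s))
  }
  stats::setNames(sample.int(max_count, k, replace = TRUE), seqs)
}

# Naive full-scan mapping oracle over plain annotation tables.
# exons/bodies: data.frames with chrom, start (0-based), end, gene_id.
oracle_annotation_tables <- function(gtf) {
  gr <- rtracklayer::import(gtf)
  gr <- gr[gr$type == "exon"]
  exons <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_id = gr$gene_id,
    stringsAsFactors = FALSE)
  bodies <- do.call(rbind, lapply(split(exons, exons$gene_id),
                                  function(h) {
    data.frame(chrom = h$chrom[1L], start = min(h$start),
               end = max(h$end), gene_id = h$gene_id[1L],
               stringsAsFactors = FALSE)
  }))
  list(exons = exons, bodies = bodies)
}

oracle_assign <- function(chrom, bstart, bend, tabs,
                          ercc_prefix = "ERCC-", min_overlap = 1L) {
  if (is.na(chrom)) {
    return(list(status = "unaligned", gene_id = NA_character_))
  }
  if (startsWith(chrom, ercc_prefix)) {
    return(list(status = "ercc", gene_id = chrom))
  }
  per_gene <- function(df) {
    hit <- df[df$chrom == chrom, , drop = FALSE]
    if (!nrow(hit)) return(character(0))
    ov <- numeric(0)
    for (g in unique(hit$gene_id)) {
      h <- hit[hit$gene_id == g, , drop = FALSE]
      tot <- 0L
      for (r in seq_len(nrow(h))) {
        for (b in seq_along(bstart)) {
          tot <- tot + max(0L, min(h$end[r], bend[b]) -
                             max(h$start[r], bstart[b]))
        }
      }
      ov[g] <- tot
    }
    names(ov)[ov >= min_overlap]
  }
  g <- per_gene(tabs$exons)
  if (length(g) == 1L) {
    return(list(status = "exon", gene_id = g))
  }
  if (length(g) > 1L) {
    return(list(status = "ambiguous", gene_id = NA_character_))
  }
  if (length(per_gene(tabs$bodies))) {
    return(list(status = "intron", gene_id = NA_character_))
  }
  list(status = "aligned_elsewhere", gene_id = NA_character_)
}

# genes x cells truth matrix from a simulate_experiment() result
truth_matrix <- function(sim, gene_ids, cell_ids) {
  tm <- matrix(0L, length(gene_ids), length(cell_ids),
               dimnames = list(gene_ids, cell_ids))
  tm[cbind(sim$molecules$gene_id, sim$molecules$cell_id)] <-
    sim$molecules$molecules
  tm
}
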