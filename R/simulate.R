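# Ground-truthed synthetic data generators. Every generator is
# seed-deterministic and writes its truth tables next to the data, so
# each pipeline stage can be tested end-to-end without external
# downloads. The scale is deliberately small (tens of cells, tens of
# genes, tens of thousands of reads) so a full run takes seconds.

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

mutate_base <- function(seqs, pos) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_along(seqs), function(i) {
    cur <- substr(seqs[i], pos[i], pos[i])
    new <- sample(setdiff(bases, cur), 1L)
    paste0(substr(seqs[i], 1L, pos[i] - 1L), new,
           substr(seqs[i], pos[i] + 1L, nchar(seqs[i])))
  }, character(1))
}

#' Generate well-separated cell barcodes
#'
#' Draws `n` random barcodes of length `len` whose pairwise hamming
#' distance is at least `min_dist`, by greedy rejection sampling. A
#' minimum distance of 4 guarantees that a single sequencing error is
#' uniquely correctable and that two errors can never reach another
#' barcode's 1-mismatch neighbourhood.
#'
#' @param n number of barcodes.
#' @param len barcode length in bases.
#' @param min_dist minimum pairwise hamming distance.
#' @param seed RNG seed.
#' @return Character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, len = 8L, min_dist = 4L,
                              seed = NULL) {
  with_local_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- random_dna(1L, len)
      if (!length(out) ||
          min(hamming_distance(rep(cand, length(out)), out)) >=
            min_dist) {
        out <- c(out, cand)
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > 20000L) {
          stop("cannot place ", n, " barcodes of length ", len,
               " at pairwise distance ", min_dist,
               "; increase len or lower min_dist", call. = FALSE)
        }
      }
    }
    out
  })
}

# k UMIs of length len at pairwise hamming distance >= min_dist
sample_umis <- function(k, len, min_dist = 3L) {
  out <- character(0)
  while (length(out) < k) {
    cand <- random_dna(1L, len)
    if (!length(out) ||
        min(hamming_distance(rep(cand, length(out)), out)) >=
          min_dist) {
      out <- c(out, cand)
    }
  }
  out
}

#' Build a toy gene annotation for simulations
#'
#' Lays out a small deterministic genome: two-exon genes on `chr1`
#' (500 bp exons separated by a 300 bp intron, 2 kb gene spacing), an
#' overlapping gene pair on `chr2` whose exons share a 300 bp window
#' (to exercise ambiguous assignment), mitochondrial genes on `MT`,
#' and single-exon spike-in control contigs named `ERCC-0001`, ...
#' The annotation is written as GTF.
#'
#' @param gtf output GTF path.
#' @param n_genes total endogenous genes on chr1/chr2 (>= 3; two of
#'   them form the overlapping pair on chr2).
#' @param n_ercc number of spike-in control contigs.
#' @param n_mito number of mitochondrial genes.
#' @return A list with `gtf` (the path), `genes` (a data.frame of
#'   0-based exon coordinates used by the read placers) and
#'   `contig_lengths` (named integer vector).
#' @export
make_toy_annotation <- function(gtf, n_genes = 20L, n_ercc = 8L,
                                n_mito = 2L) {
  stopifnot(n_genes >= 3L)
  rows <- list()
  genes <- list()
  add_exon <- function(chrom, s0, e0, gid, gname) {
    rows[[length(rows) + 1L]] <<- sprintf(
      '%s\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_name "%s";',
      chrom, s0 + 1L, e0, gid, gname)
    genes[[length(genes) + 1L]] <<- data.frame(
      chrom = chrom, start = s0, end = e0, gene_id = gid,
      stringsAsFactors = FALSE)
  }
  n_chr1 <- n_genes - 2L
  for (i in seq_len(n_chr1)) {
    s <- 2000L * i
    gid <- sprintf("g%03d", i)
    add_exon("chr1", s, s + 500L, gid, gid)
    add_exon("chr1", s + 800L, s + 1300L, gid, gid)
  }
  # overlapping pair: exons share [1300, 1600)
  add_exon("chr2", 1000L, 1600L, "gOVA", "gOVA")
  add_exon("chr2", 1300L, 1900L, "gOVB", "gOVB")
  for (i in seq_len(n_mito)) {
    s <- 1000L * i
    gid <- sprintf("mt-g%d", i)
    add_exon("MT", s, s + 500L, gid, paste0("mt-Nd", i))
  }
  for (i in seq_len(n_ercc)) {
    nm <- sprintf("ERCC-%04d", i)
    add_exon(nm, 0L, 500L, nm, nm)
  }
  writeLines(unlist(rows), gtf)
  lens <- c(
    stats::setNames(2000L * (n_chr1 + 2L), "chr1"),
    chr2 = 4000L, MT = 1000L * (n_mito + 2L),
    stats::setNames(rep(600L, n_ercc),
                    sprintf("ERCC-%04d", seq_len(n_ercc))))
  list(gtf = gtf, genes = do.call(rbind, genes),
       contig_lengths = lens)
}

# Positions (0-based) realising a given status for the toy layout.
# Returns list(chrom, pos) for one read of length read_len.
place_read <- function(status, gene, anno, read_len) {
  g <- anno$genes
  switch(status,
    exon = {
      ex <- g[g$gene_id == gene, , drop = FALSE]
      # for the overlapping pair keep reads out of the shared window
      if (gene == "gOVA") ex$end <- 1300L
      if (gene == "gOVB") ex$start <- 1600L
      i <- sample(nrow(ex), 1L)
      p <- ex$start[i] +
        sample.int(ex$end[i] - ex$start[i] - read_len + 1L, 1L) - 1L
      list(chrom = ex$chrom[i], pos = p)
    },
    ercc = {
      list(chrom = gene,
           pos = sample.int(500L - read_len + 1L, 1L) - 1L)
    },
    intron = {
      ex <- g[g$chrom == "chr1", , drop = FALSE]
      gid <- sample(unique(ex$gene_id), 1L)
      s <- min(ex$start[ex$gene_id == gid])
      list(chrom = "chr1",
           pos = s + 500L +
             sample.int(300L - read_len + 1L, 1L) - 1L)
    },
    ambiguous = {
      list(chrom = "chr2",
           pos = 1300L + sample.int(300L - read_len + 1L, 1L) - 1L)
    },
    aligned_elsewhere = {
      ex <- g[g$chrom == "chr1", , drop = FALSE]
      gid <- sample(unique(ex$gene_id), 1L)
      s <- min(ex$start[ex$gene_id == gid])
      # intergenic window after the gene body
      list(chrom = "chr1",
           pos = s + 1350L + sample.int(550L - read_len, 1L) - 1L)
    },
    unaligned = list(chrom = NA_character_, pos = NA_integer_),
    stop("unknown status ", status)
  )
}

write_sam_bam <- function(recs, contig_lengths, bam, sort = TRUE) {
  hd <- c("@HD\tVN:1.6\tSO:coordinate",
          sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                  as.integer(contig_lengths)))
  mapped <- !is.na(recs$chrom)
  recs$flag <- ifelse(mapped, 0L, 4L)
  if (sort) {
    ord <- order(!mapped,
                 match(recs$chrom, names(contig_lengths)), recs$pos)
    recs <- recs[ord, , drop = FALSE]
  }
  body <- paste(
    recs$name, recs$flag,
    ifelse(is.na(recs$chrom), "*", recs$chrom),
    ifelse(is.na(recs$pos), 0L, recs$pos + 1L),
    ifelse(is.na(recs$chrom), 0L, 60L),
    ifelse(is.na(recs$chrom), "*",
           paste0(nchar(recs$seq), "M")),
    "*", 0L, 0L, recs$seq, strrep("I", nchar(recs$seq)),
    sep = "\t")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(hd, body), sam)
  Rsamtools::asBam(sam, destination = sub("\\.bam$", "", bam),
                   overwrite = TRUE, indexDestination = FALSE)
  invisible(bam)
}

#' Simulate a complete ground-truthed experiment
#'
#' Generates a toy annotation, a set of well-separated cell barcodes,
#' per-(cell, gene) molecule counts, PCR-duplicated reads with
#' optional barcode and UMI sequencing errors, and writes:
#' paired FASTQ files (`R1.fastq.gz` with barcode + UMI,
#' `R2.fastq.gz` with the transcript), the corresponding aligned BAM
#' (`aligned.bam`, coordinate sorted, read names already carrying the
#' observed barcode/UMI header), the annotation GTF, a barcode
#' whitelist, and truth tables (`truth_reads.csv`,
#' `truth_molecules.csv`).
#'
#' Error model: a fraction `bc_error_frac` of reads receive exactly
#' one substitution in the barcode; when `umi_errors` is on, every
#' molecule with at least 4 duplicate reads diverts
#' `floor((d - 1) / 3)` of them to a 1-substitution UMI variant, so
#' the true UMI always keeps more than twice the variant's reads and
#' greedy deduplication can recover the exact molecule count. True
#' UMIs within a (cell, gene) pair are kept at pairwise hamming
#' distance >= 3 so variants never collide. Noise reads with intron /
#' intergenic / ambiguous / unmapped placements are added on top and
#' carry no molecule truth.
#'
#' @param out_dir output directory (created).
#' @param n_cells,n_genes,n_ercc,n_mito experiment dimensions.
#' @param barcode_len,umi_len barcode and UMI length in bases.
#' @param lambda mean molecules per (cell, gene) (Poisson).
#' @param lambda_ercc mean molecules per (cell, spike-in species).
#' @param dup_range inclusive range of PCR duplicates per molecule.
#' @param bc_error_frac fraction of reads with one barcode error.
#' @param umi_errors inject recoverable UMI error variants?
#' @param noise_frac named fractions (of molecule reads) of extra
#'   `intron`, `ambiguous`, `aligned_elsewhere`, `unaligned` reads.
#' @param read_len transcript read length.
#' @param seed RNG seed; identical seeds give identical files.
#' @return A list with paths (`r1`, `r2`, `bam`, `gtf`, `whitelist`),
#'   the `structure` ([read_structure()]) describing the reads, the
#'   `barcodes` data.frame, and truth tables `reads` and `molecules`.
#' @export
simulate_experiment <- function(out_dir,
                                n_cells = 24L, n_genes = 20L,
                                n_ercc = 8L, n_mito = 2L,
                                barcode_len = 8L, umi_len = 6L,
                                lambda = 5, lambda_ercc = 2,
                                dup_range = c(1L, 20L),
                                bc_error_frac = 0,
                                umi_errors = TRUE,
                                noise_frac = c(intron = 0.04,
                                               ambiguous = 0.02,
                                               aligned_elsewhere = 0.03,
                                               unaligned = 0.03),
                                read_len = 80L,
                                seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_local_seed(seed, {
    anno <- make_toy_annotation(file.path(out_dir, "annotation.gtf"),
                                n_genes, n_ercc, n_mito)
    barcodes <- generate_barcodes(n_cells, barcode_len, min_dist = 4L)
    cells <- sprintf("cell_%03d", seq_len(n_cells))
    wl <- data.frame(cell_id = cells, barcode = barcodes,
                     stringsAsFactors = FALSE)
    write_whitelist(wl, file.path(out_dir, "whitelist.txt"))

    endo <- setdiff(unique(anno$genes$gene_id),
                    grep("^ERCC-", anno$genes$gene_id, value = TRUE))
    ercc <- grep("^ERCC-", unique(anno$genes$gene_id), value = TRUE)

    # molecule truth
    grid <- rbind(
      expand.grid(cell = seq_len(n_cells), gene = endo,
                  stringsAsFactors = FALSE),
      expand.grid(cell = seq_len(n_cells), gene = ercc,
                  stringsAsFactors = FALSE))
    grid$lambda <- ifelse(grid$gene %in% ercc, lambda_ercc, lambda)
    grid$n_mol <- stats::rpois(nrow(grid), grid$lambda)
    grid <- grid[grid$n_mol > 0L, , drop = FALSE]

    reads <- list()
    mol_truth <- list()
    rid <- 0L
    for (i in seq_len(nrow(grid))) {
      ci <- grid$cell[i]; gene <- grid$gene[i]
      k <- grid$n_mol[i]
      umis <- sample_umis(k, umi_len, min_dist = 3L)
      status <- if (gene %in% ercc) "ercc" else "exon"
      for (m in seq_len(k)) {
        d <- sample(seq.int(dup_range[1L], dup_range[2L]), 1L)
        err <- 0L
        umi_obs <- rep(umis[m], d)
        if (umi_errors && d >= 4L) {
          err <- (d - 1L) %/% 3L
          var <- mutate_base(umis[m],
                             sample.int(umi_len, 1L))
          umi_obs[seq_len(err)] <- var
        }
        for (r in seq_len(d)) {
          rid <- rid + 1L
          pl <- place_read(status, gene, anno, read_len)
          reads[[rid]] <- data.frame(
            name = sprintf("r%06d", rid), cell_id = cells[ci],
            barcode = barcodes[ci], umi = umi_obs[r],
            gene_id = gene, status = status,
            chrom = pl$chrom, pos = pl$pos,
            stringsAsFactors = FALSE)
        }
      }
      mol_truth[[i]] <- data.frame(cell_id = cells[ci],
                                   gene_id = gene, molecules = k,
                                   stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, c(reads, list(make.row.names = FALSE)))
    mol_truth <- do.call(rbind,
                         c(mol_truth, list(make.row.names = FALSE)))

    # noise reads: present in FASTQ/BAM, never in the count matrix
    n_molreads <- nrow(reads)
    noise <- list()
    for (st in names(noise_frac)) {
      nn <- round(noise_frac[[st]] * n_molreads)
      for (j in seq_len(nn)) {
        rid <- rid + 1L
        ci <- sample.int(n_cells, 1L)
        pl <- place_read(st, NA_character_, anno, read_len)
        noise[[length(noise) + 1L]] <- data.frame(
          name = sprintf("r%06d", rid), cell_id = cells[ci],
          barcode = barcodes[ci], umi = random_dna(1L, umi_len),
          gene_id = NA_character_, status = st,
          chrom = pl$chrom, pos = pl$pos,
          stringsAsFactors = FALSE)
      }
    }
    if (length(noise)) {
      reads <- rbind(reads,
                     do.call(rbind, c(noise,
                                      list(make.row.names = FALSE))))
    }

    # observed barcode: inject one substitution in a read fraction
    n <- nrow(reads)
    reads$barcode_obs <- reads$barcode
    reads$bc_error <- FALSE
    if (bc_error_frac > 0) {
      hit <- sample.int(n, round(bc_error_frac * n))
      reads$barcode_obs[hit] <- mutate_base(
        reads$barcode[hit], sample(barcode_len, length(hit),
                                   replace = TRUE))
      reads$bc_error[hit] <- TRUE
    }
    reads <- reads[sample.int(n), , drop = FALSE]

    # FASTQ pair: R1 = barcode + UMI, R2 = transcript
    r1seq <- paste0(reads$barcode_obs, reads$umi)
    r2seq <- random_dna(n, read_len)
    q1 <- strrep("I", barcode_len + umi_len)
    q2 <- strrep("I", read_len)
    r1 <- file.path(out_dir, "R1.fastq.gz")
    r2 <- file.path(out_dir, "R2.fastq.gz")
    write_fq <- function(path, seqs, quals) {
      if (file.exists(path)) file.remove(path)
      ShortRead::writeFastq(ShortRead::ShortReadQ(
        sread = Biostrings::DNAStringSet(seqs),
        quality = Biostrings::BStringSet(quals),
        id = Biostrings::BStringSet(reads$name)),
        path, mode = "w", compress = TRUE)
    }
    write_fq(r1, r1seq, rep(q1, n))
    write_fq(r2, r2seq, rep(q2, n))

    # aligned BAM with the reformatted header already in the name
    bam <- file.path(out_dir, "aligned.bam")
    recs <- data.frame(
      name = encode_read_header(reads$barcode_obs, reads$umi,
                                reads$name),
      chrom = reads$chrom, pos = reads$pos, seq = r2seq,
      stringsAsFactors = FALSE)
    write_sam_bam(recs, anno$contig_lengths, bam)

    utils::write.csv(reads, file.path(out_dir, "truth_reads.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(mol_truth,
                     file.path(out_dir, "truth_molecules.csv"),
                     row.names = FALSE, quote = FALSE)
    list(
      r1 = r1, r2 = r2, bam = bam, gtf = anno$gtf,
      whitelist = file.path(out_dir, "whitelist.txt"),
      structure = read_structure(
        bc1_start = 0L, bc1_len = barcode_len,
        umi_start = barcode_len, umi_len = umi_len,
        umi_read = 1L, transcript_read = 2L),
      barcodes = wl, reads = reads, molecules = mol_truth,
      annotation = anno
    )
  })
}

#' Simulate barcoded read pairs only
#'
#' Thin wrapper around [simulate_experiment()] that keeps the FASTQ
#' pair and the truth tables (no BAM is needed, e.g. for reformatting
#' and barcode-detection tests).
#'
#' @inheritParams simulate_experiment
#' @param ... passed to [simulate_experiment()].
#' @return See [simulate_experiment()].
#' @export
simulate_reads <- function(out_dir, seed = 1L, ...) {
  simulate_experiment(out_dir, seed = seed, ...)
}

#' Simulate alignments with a prescribed mapping-status mixture
#'
#' Writes a toy annotation and a BAM whose primary alignments realise
#' an exact requested mixture over the six mapping statuses, for
#' testing the feature-assignment rules. Read names carry a dummy
#' barcode/UMI header. One exon read is always placed across a bin
#' boundary of the default index bin width to exercise the
#' boundary-spanning path.
#'
#' @param out_dir output directory.
#' @param n_reads total primary alignments.
#' @param status_mix named numeric vector of proportions over
#'   `exon`, `intron`, `ambiguous`, `aligned_elsewhere`, `unaligned`,
#'   `ercc` (normalised internally).
#' @param read_len alignment length on the reference.
#' @param seed RNG seed.
#' @return A list with `bam`, `gtf` and `truth` (data.frame with the
#'   expected status and, for exon/ercc reads, the expected gene).
#' @export
simulate_alignments <- function(out_dir, n_reads = 2000L,
                                status_mix = c(exon = 0.6,
                                               intron = 0.1,
                                               ambiguous = 0.05,
                                               aligned_elsewhere = 0.1,
                                               unaligned = 0.05,
                                               ercc = 0.1),
                                read_len = 80L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_local_seed(seed, {
    anno <- make_toy_annotation(file.path(out_dir, "annotation.gtf"),
                                n_genes = 10L, n_ercc = 4L)
    mix <- status_mix / sum(status_mix)
    counts <- floor(mix * n_reads)
    rem <- n_reads - sum(counts)
    if (rem > 0L) {
      counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    }
    endo <- grep("^g", unique(anno$genes$gene_id), value = TRUE)
    ercc <- grep("^ERCC-", unique(anno$genes$gene_id), value = TRUE)
    truth <- list()
    rid <- 0L
    for (st in names(counts)) {
      for (j in seq_len(counts[[st]])) {
        rid <- rid + 1L
        gene <- switch(st,
          exon = sample(endo, 1L),
          ercc = sample(ercc, 1L),
          NA_character_)
        pl <- place_read(st, gene, anno, read_len)
        truth[[rid]] <- data.frame(
          name = sprintf("r%06d", rid), status = st,
          gene_id = gene, chrom = pl$chrom, pos = pl$pos,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    # force one exon read across a 500-multiple bin boundary: gene
    # g001 exon2 covers [2800, 3300), which spans 3000
    boundary <- which(truth$status == "exon")[1L]
    truth$gene_id[boundary] <- "g001"
    truth$chrom[boundary] <- "chr1"
    truth$pos[boundary] <- 3000L - read_len %/% 2L
    truth <- truth[sample.int(nrow(truth)), , drop = FALSE]

    bam <- file.path(out_dir, "alignments.bam")
    recs <- data.frame(
      name = encode_read_header("ACGTACGT", "AACCGG", truth$name),
      chrom = truth$chrom, pos = truth$pos,
      seq = random_dna(nrow(truth), read_len),
      stringsAsFactors = FALSE)
    write_sam_bam(recs, anno$contig_lengths, bam)
    utils::write.csv(truth, file.path(out_dir, "truth_alignments.csv"),
                     row.names = FALSE, quote = FALSE)
    list(bam = bam, gtf = anno$gtf, truth = truth, annotation = anno)
  })
}

#' Simulate a per-cell QC metric table from a good/poor mixture
#'
#' Draws `n_cells` cells from a Gaussian QC-metric model: good cells
#' around typical values of log-molecules, genes detected and
#' mitochondrial percentage, and a `poor_fraction` of damaged cells
#' shifted by `shift_sd` standard deviations (down on molecules and
#' genes, up on mitochondrial content). With `poor_fraction = 0` the
#' table is a single multivariate Gaussian, the null case used for
#' calibration of [detect_outliers()].
#'
#' @param n_cells number of cells.
#' @param poor_fraction fraction of poor-quality cells.
#' @param shift_sd shift of the poor population in SD units.
#' @param seed RNG seed.
#' @return A list with `qc` (data.frame with `cell_id`,
#'   `log10_molecules`, `genes_detected`, `pct_mito`) and `truth`
#'   (logical vector, `TRUE` for poor cells).
#' @export
simulate_qc_table <- function(n_cells = 2000L, poor_fraction = 0,
                              shift_sd = 3, seed = 1L) {
  with_local_seed(seed, {
    n_poor <- round(poor_fraction * n_cells)
    poor <- c(rep(TRUE, n_poor), rep(FALSE, n_cells - n_poor))
    mu <- c(log10_molecules = 4, genes_detected = 3000, pct_mito = 5)
    sd <- c(log10_molecules = 0.3, genes_detected = 400,
            pct_mito = 1.5)
    shift <- c(-1, -1, 1) * shift_sd * sd
    qc <- data.frame(
      cell_id = sprintf("cell_%04d", seq_len(n_cells)),
      log10_molecules = stats::rnorm(n_cells, mu[1L], sd[1L]),
      genes_detected = stats::rnorm(n_cells, mu[2L], sd[2L]),
      pct_mito = stats::rnorm(n_cells, mu[3L], sd[3L]),
      stringsAsFactors = FALSE)
    for (j in 1:3) {
      qc[poor, j + 1L] <- qc[poor, j + 1L] + shift[j]
    }
    ord <- sample.int(n_cells)
    list(qc = qc[ord, , drop = FALSE], truth = poor[ord])
  })
}
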