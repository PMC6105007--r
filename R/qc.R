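# Per-cell QC metric aggregation and the three-stage multivariate
# outlier detector (Mahalanobis pre-filter, Gaussian mixture model,
# within-component Mahalanobis distance) for flagging low-quality
# cells.

# run code with a locally-seeded RNG, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Aggregate per-cell quality-control metrics across pipeline stages
#'
#' Combines the per-cell mapping-status counts (from [demultiplex()]),
#' the UMI deduplication statistics (from [count_genes()]) and the
#' gene count matrix into one table with a row per cell: total reads,
#' molecules, genes detected, the percentage of reads in each mapping
#' category, the percentage of counts from mitochondrial and ribosomal
#' genes, and -- when spike-in controls are annotated -- the spike-in
#' recovery rate (fraction of annotated control species detected with
#' at least one molecule).
#'
#' Ribosomal genes default to symbols matching `Rps`/`Rpl` (case
#' insensitive); mitochondrial genes are those located on the
#' configured mitochondrial reference names of the index.
#'
#' @param cell_stats per-cell mapping-status counts (the `cell_stats`
#'   element returned by [demultiplex()]).
#' @param dedup_stats per-cell deduplication statistics (from
#'   [count_genes()]).
#' @param mat gene count matrix, genes x cells.
#' @param index the [build_feature_index()] used for assignment.
#' @param ribo_pattern regular expression on gene symbols (falling
#'   back to gene ids) identifying ribosomal protein genes.
#' @return A data.frame with one row per cell. Mapping percentages sum
#'   to 100 for every cell with at least one read.
#' @export
compute_qc_table <- function(cell_stats, dedup_stats, mat, index,
                             ribo_pattern = "^Rp[sl]") {
  cells <- colnames(mat)
  for (nm in list(cell_stats$cell_id, dedup_stats$cell_id)) {
    if (!setequal(nm, cells)) {
      stop("cell sets differ between inputs; missing: ",
           paste(utils::head(c(setdiff(cells, nm),
                               setdiff(nm, cells)), 5L),
                 collapse = ", "), call. = FALSE)
    }
  }
  cs <- cell_stats[match(cells, cell_stats$cell_id), , drop = FALSE]
  ds <- dedup_stats[match(cells, dedup_stats$cell_id), , drop = FALSE]

  statuses <- intersect(MAPPING_STATUSES, names(cs))
  total <- rowSums(cs[, statuses, drop = FALSE])
  pct <- function(x) ifelse(total > 0L, 100 * x / total, 0)

  genes <- rownames(mat)
  ercc <- intersect(index$ercc_ids, genes)
  endo <- setdiff(genes, ercc)
  mito <- intersect(index$mito_genes, genes)
  sym <- index$genes$gene_name
  ribo_by <- ifelse(is.na(sym), index$genes$gene_id, sym)
  ribo <- index$genes$gene_id[grepl(ribo_pattern, ribo_by,
                                    ignore.case = TRUE)]
  ribo <- intersect(ribo, genes)

  molecules <- colSums(mat)
  endo_counts <- colSums(mat[endo, , drop = FALSE])
  qc <- data.frame(
    cell_id = cells,
    total_reads = as.integer(total),
    molecules = as.integer(molecules),
    genes_detected = as.integer(
      colSums(mat[endo, , drop = FALSE] > 0L)),
    stringsAsFactors = FALSE
  )
  for (s in statuses) qc[[paste0("pct_mapped_", s)]] <- pct(cs[[s]])
  qc$pct_mito <- ifelse(
    molecules > 0L,
    100 * colSums(mat[mito, , drop = FALSE]) / molecules, 0)
  qc$pct_ribo <- ifelse(
    molecules > 0L,
    100 * colSums(mat[ribo, , drop = FALSE]) / molecules, 0)
  if (length(ercc)) {
    qc$ercc_recovery <- colSums(mat[ercc, , drop = FALSE] > 0L) /
      length(ercc)
    qc$pct_counts_ercc <- ifelse(
      molecules > 0L,
      100 * colSums(mat[ercc, , drop = FALSE]) / molecules, 0)
  }
  qc$reads_in <- ds$reads_in
  qc$distinct_umis <- ds$distinct_umis
  qc$molecules_out <- ds$molecules_out
  qc$umis_corrected <- ds$umis_corrected
  qc
}

# covariance with a small ridge so near-collinear metrics stay
# invertible; fails loudly when truly singular
regularized_cov <- function(x) {
  s <- stats::cov(x)
  if (anyNA(s)) {
    stop("QC metric covariance is undefined; remove constant or ",
         "missing metrics", call. = FALSE)
  }
  s <- s + diag(1e-8 * mean(diag(s)), ncol(x))
  inv <- tryCatch(solve(s), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    stop("covariance of the QC metrics is singular even after ",
         "regularization; remove a constant or collinear metric",
         call. = FALSE)
  }
  s
}

#' Squared Mahalanobis distance
#'
#' Computes `d^2 = (x - center)' Sigma^-1 (x - center)` for each row
#' of `x`. Under an identity covariance this equals the squared
#' Euclidean distance. Under multivariate normality, `d^2` follows a
#' chi-square distribution with `ncol(x)` degrees of freedom, which is
#' what the outlier thresholds of [detect_outliers()] are based on.
#'
#' @param x numeric matrix (observations in rows) or vector.
#' @param center distribution center.
#' @param cov covariance matrix (symmetric positive definite after the
#'   internal ridge regularization).
#' @return Numeric vector of squared distances.
#' @export
qc_mahalanobis <- function(x, center, cov) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stats::mahalanobis(x, center, cov)
}

# signed direction of each QC metric: +1 when larger values indicate a
# healthier cell, -1 when larger values indicate damage
metric_sign <- function(metrics) {
  ifelse(grepl("mito|ribo|unaligned|ambiguous|elsewhere|intron",
               metrics), -1, 1)
}

#' Detect low-quality cells with a three-stage multivariate procedure
#'
#' Flags cells whose QC metrics are jointly atypical, instead of
#' thresholding single metrics such as the read count. The procedure
#' has three stages:
#'
#' 1. **Pre-filter.** Squared Mahalanobis distances are computed for
#'    all cells against the full-sample mean and covariance of the
#'    standardized metrics. Cells beyond the
#'    `chi-square(extreme_quantile, df = k)` quantile are removed
#'    (and flagged) before model fitting, so single gross outliers
#'    cannot distort the mixture fit. This stage is a guard against
#'    extremes, hence its quantile is stricter than `conf`.
#' 2. **Mixture model.** A Gaussian mixture with up to `comp`
#'    components (selected by BIC) is fitted to the remaining cells.
#'    When more than one component is supported, components whose
#'    means are dominated by the best component on the majority of
#'    metrics -- lower molecule and gene counts, higher mitochondrial
#'    fraction -- are flagged wholesale as low quality. With
#'    `comp = 1` this stage is skipped.
#' 3. **Within-component distance.** Mahalanobis distances are
#'    recomputed among the cells of the highest-quality component and
#'    cells beyond the `chi-square(conf, df = k)` quantile are
#'    flagged.
#'
#' The union of the three stages is returned. Metrics are z-scored
#' before any distance or mixture computation, so results are
#' invariant to affine rescaling of individual metrics.
#'
#' @param qc a QC table from [compute_qc_table()] (or any data.frame
#'   with the selected metric columns and a `cell_id` column).
#' @param metrics character vector of metric columns. The derived
#'   metric `"log10_molecules"` (log10 of molecules + 1) is computed
#'   on the fly. `NULL` selects, among the canonical five
#'   (log10_molecules, genes_detected, pct_mito, pct_ribo,
#'   ercc_recovery), those that are present and non-constant.
#' @param comp maximum number of mixture components; 1 or 2 suits
#'   plate data with few poor cells, 2 or 3 droplet data where a
#'   larger poor-quality population is expected.
#' @param conf confidence level for the outlier distance threshold.
#' @param extreme_quantile chi-square quantile of the stage-1
#'   pre-filter.
#' @param seed optional integer for reproducible mixture fitting.
#' @return A data.frame with one row per cell: `cell_id`,
#'   `is_outlier`, `stage` (`pre_filter`, `low_component`, `distance`
#'   or `NA` for good cells), `mahalanobis_distance` (stage-1 squared
#'   distance) and `component` (mixture component label, `NA` for
#'   pre-filtered cells).
#' @export
detect_outliers <- function(qc, metrics = NULL, comp = 1L,
                            conf = 0.99, extreme_quantile = 0.999,
                            seed = NULL) {
  stopifnot(comp >= 1L, conf > 0, conf < 1)
  qc <- as.data.frame(qc)
  if (!is.null(qc$molecules)) {
    qc$log10_molecules <- log10(qc$molecules + 1)
  }
  if (is.null(metrics)) {
    cand <- c("log10_molecules", "genes_detected", "pct_mito",
              "pct_ribo", "ercc_recovery")
    metrics <- cand[cand %in% names(qc)]
    metrics <- metrics[vapply(metrics, function(m) {
      stats::sd(qc[[m]]) > 0
    }, logical(1))]
  }
  missing <- setdiff(metrics, names(qc))
  if (length(missing)) {
    stop("QC table lacks metric column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  k <- length(metrics)
  n <- nrow(qc)
  if (n < 2L * k) {
    stop("need at least ", 2L * k, " cells for ", k, " metrics",
         call. = FALSE)
  }
  x <- scale(as.matrix(qc[, metrics, drop = FALSE]))
  sgn <- metric_sign(metrics)

  out <- data.frame(
    cell_id = qc$cell_id, is_outlier = FALSE, stage = NA_character_,
    mahalanobis_distance = NA_real_, component = NA_integer_,
    stringsAsFactors = FALSE)

  # stage 1: pre-filter gross extremes on the pooled fit
  d2 <- qc_mahalanobis(x, colMeans(x), regularized_cov(x))
  out$mahalanobis_distance <- d2
  thr1 <- stats::qchisq(extreme_quantile, df = k)
  pre <- d2 > thr1
  out$is_outlier[pre] <- TRUE
  out$stage[pre] <- "pre_filter"
  keep <- which(!pre)

  # stage 2: mixture fit on the remaining cells
  comp_of <- rep(1L, length(keep))
  best_comp <- 1L
  if (comp > 1L) {
    fit <- with_local_seed(seed, tryCatch(
      Mclust(x[keep, , drop = FALSE], G = seq_len(comp),
             verbose = FALSE),
      error = function(e) NULL))
    if (is.null(fit)) {
      warning("mixture fit failed; falling back to a single component",
              call. = FALSE)
    } else if (fit$G > 1L) {
      comp_of <- fit$classification
      means <- t(fit$parameters$mean)    # G x k
      score <- as.numeric(means %*% sgn) / k
      best_comp <- which.max(score)
      for (g in seq_len(fit$G)) {
        if (g == best_comp) next
        dominated <- sum(sgn * (means[g, ] - means[best_comp, ]) < 0)
        if (dominated > k / 2) {
          low <- keep[comp_of == g]
          out$is_outlier[low] <- TRUE
          out$stage[low] <- "low_component"
        }
      }
    }
  }
  out$component[keep] <- comp_of

  # stage 3: distance within the highest-quality component
  top <- keep[comp_of == best_comp & !out$is_outlier[keep]]
  if (length(top) > k + 1L) {
    xt <- x[top, , drop = FALSE]
    d2t <- qc_mahalanobis(xt, colMeans(xt), regularized_cov(xt))
    far <- d2t > stats::qchisq(conf, df = k)
    out$is_outlier[top[far]] <- TRUE
    out$stage[top[far]] <- "distance"
  }
  out
}
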