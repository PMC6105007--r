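# QC plotting surface: barcode-match bar plots, per-cell stacked
# mapping-rate bars ordered by exon rate, and the pairwise QC scatter
# matrix coloured by outlier status.

#' Bar plot of barcode-matching categories
#'
#' One bar per matching category (exact, mismatch, unmatched,
#' ambiguous). With a `run` column present in `stats`, runs are shown
#' side by side so experiments can be compared.
#'
#' @param stats a `demux_stats` object, or a data.frame with columns
#'   `metric`, `value` and optionally `run`.
#' @return A ggplot object.
#' @export
plot_demux_stats <- function(stats) {
  df <- if (is.data.frame(stats)) stats else as.data.frame(stats)
  df$metric <- factor(df$metric,
                      levels = c("exact_match", "mismatch_match",
                                 "unmatched", "ambiguous"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$metric,
                                        y = .data$value))
  if ("run" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$run),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(fill = "steelblue")
  }
  p + ggplot2::labs(x = "barcode match category", y = "reads",
                    title = "Cell barcode matching") +
    ggplot2::theme_minimal()
}

#' Stacked per-cell mapping-rate bars ordered by exon rate
#'
#' Each cell is a bar split by the fraction of its reads in each
#' mapping status; cells are ordered by decreasing exon mapping rate.
#'
#' @param cell_stats per-cell mapping-status counts (the `cell_stats`
#'   element of [demultiplex()]).
#' @return A ggplot object.
#' @export
plot_mapping_rates <- function(cell_stats) {
  cs <- as.data.frame(cell_stats)
  statuses <- intersect(MAPPING_STATUSES, names(cs))
  total <- rowSums(cs[, statuses, drop = FALSE])
  total[total == 0] <- 1
  exon_rate <- cs$exon / total
  cs$cell_id <- factor(cs$cell_id,
                       levels = cs$cell_id[order(-exon_rate,
                                                 cs$cell_id)])
  long <- do.call(rbind, lapply(statuses, function(s) {
    data.frame(cell_id = cs$cell_id, status = s,
               fraction = cs[[s]] / total)
  }))
  long$status <- factor(long$status, levels = statuses)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_id,
                                     y = .data$fraction,
                                     fill = .data$status)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = "cells (ordered by exon mapping rate)",
                  y = "fraction of reads",
                  title = "Per-cell mapping rates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Pairwise scatter matrix of QC metrics coloured by outlier status
#'
#' Draws every pair of the chosen QC metrics as a scatter panel with
#' outlier cells in a distinct colour, the standard visual check on
#' the automatic outlier calls.
#'
#' @param qc a QC table ([compute_qc_table()]).
#' @param outliers outlier calls ([detect_outliers()]).
#' @param metrics metric columns to plot; defaults to the outlier
#'   detector's canonical set present in `qc`.
#' @return A ggplot object (faceted over metric pairs).
#' @export
plot_qc_pairs <- function(qc, outliers, metrics = NULL) {
  qc <- as.data.frame(qc)
  if (!is.null(qc$molecules)) {
    qc$log10_molecules <- log10(qc$molecules + 1)
  }
  if (is.null(metrics)) {
    cand <- c("log10_molecules", "genes_detected", "pct_mito",
              "pct_ribo", "ercc_recovery")
    metrics <- cand[cand %in% names(qc)]
  }
  stopifnot(length(metrics) >= 2L)
  qc$outlier <- outliers$is_outlier[match(qc$cell_id,
                                          outliers$cell_id)]
  pairs <- utils::combn(metrics, 2L)
  long <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    data.frame(panel = paste(pairs[1L, j], "vs", pairs[2L, j]),
               x = qc[[pairs[1L, j]]], y = qc[[pairs[2L, j]]],
               outlier = qc$outlier)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, colour = "outlier",
                  title = "Pairwise QC metrics") +
    ggplot2::theme_minimal()
}
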