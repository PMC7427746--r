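# ggplot2 displays for fitted contrasts, detection calls and status
# summaries.

#' Volcano plot of moderated contrasts
#'
#' @param object An `"mscl_de"` fit.
#' @param alpha,fold Thresholds drawn and used to colour significant
#'   genes (defaults 0.05 and 2).
#' @param ... Unused.
#' @return A ggplot faceted by contrast: log2 fold change against
#'   -log10 adjusted p.
#' @method autoplot mscl_de
#' @export
autoplot.mscl_de <- function(object, alpha = 0.05, fold = 2, ...) {
  df <- dplyr::mutate(object$results,
    significant = .data$p_adj < alpha & abs(.data$signed_fc) > fold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-log2(fold), log2(fold)),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (test - reference)",
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Detection-rate plot per gene
#'
#' @param calls Long detection-call tibble from [call_detection()].
#' @param genes Optional subset of genes to display.
#' @return A ggplot of the per-gene fraction of samples with detectable
#'   signal, ordered by that fraction.
#' @export
plot_detection_rates <- function(calls, genes = NULL) {
  df <- calls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(rate = mean(.data$detected), .groups = "drop")
  if (!is.null(genes)) df <- df[df$gene %in% genes, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene, .data$rate),
                                   y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of samples detected") +
    ggplot2::theme_minimal()
}

#' Status composition plot
#'
#' @param statuses Tibble from [classify_genes()], or a named list of
#'   such tibbles (one bar group per dataset).
#' @return A stacked-count ggplot of reliability statuses.
#' @export
plot_status_composition <- function(statuses) {
  if (is.data.frame(statuses)) statuses <- list(dataset = statuses)
  df <- purrr::imap(statuses, ~ dplyr::mutate(.x, dataset = .y)) |>
    dplyr::bind_rows() |>
    dplyr::count(.data$dataset, .data$status)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes", fill = "status") +
    ggplot2::theme_minimal()
}
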