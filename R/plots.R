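#' Volcano plot of protein differential expression
#'
#' Log2 fold-change against -log10 adjusted p-value, colored by direction
#' among significant proteins (red overexpressed in tumor, blue
#' underexpressed, grey not significant).
#'
#' @param x a `moderated_fit` or its [tidy()] tibble.
#' @param alpha significance threshold on q (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, alpha = 0.05) {
  r <- if (inherits(x, "moderated_fit")) tidy(x) else tibble::as_tibble(x)
  r$status <- dplyr::case_when(
    r$q < alpha & r$log2_fc > 0 ~ "up in tumor",
    r$q < alpha & r$log2_fc < 0 ~ "down in tumor",
    .default = "not significant"
  )
  ggplot2::ggplot(r, ggplot2::aes(.data$log2_fc, -log10(.data$q),
                                  color = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(
      "up in tumor" = "#c0392b", "down in tumor" = "#2980b9",
      "not significant" = "grey70"
    )) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::labs(x = "log2 fold-change (tumor / adjacent)",
                  y = "-log10 adjusted p", color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object,... autoplot arguments.
#' @export
autoplot.moderated_fit <- function(object, alpha = 0.05, ...) {
  plot_volcano(object, alpha = alpha)
}

#' Boxplots of per-sample overall glycosylation metrics by group
#'
#' @param metrics output of [sample_glyco_metrics()].
#' @return A ggplot object, faceted by metric.
#' @export
plot_glyco_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics,
    dplyr::all_of(c("sialylation", "galactosylation", "fucosylation")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(tumor = "#2980b9",
                                          adjacent = "#c0392b")) +
    ggplot2::labs(x = NULL, y = "abundance-weighted metric", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Glycopeptide / protein fold-change overlay plot
#'
#' Bar pairs of mean glycopeptide abundance in adjacent (red) and tumor
#' (blue) tissue, with the parent protein's fold-change overlaid as black
#' diamonds on a secondary axis; the dotted line at 1 on that axis marks
#' the boundary between under- and overexpression.
#'
#' @param overlay a `glyco_overlay` from [fold_change_overlay()].
#' @return A ggplot object.
#' @export
plot_overlay <- function(overlay) {
  d <- tibble::as_tibble(overlay)
  d$label <- paste(d$protein, d$site, d$glycan)
  d$label <- factor(d$label, levels = d$label[order(d$fold_change)])
  long <- tidyr::pivot_longer(
    d, dplyr::all_of(c("mean_adjacent", "mean_tumor")),
    names_to = "tissue", values_to = "abundance"
  )
  long$tissue <- ifelse(long$tissue == "mean_tumor", "tumor", "adjacent")
  max_ab <- max(long$abundance, na.rm = TRUE)
  max_fc <- max(c(d$protein_fold_change, 1), na.rm = TRUE)
  scale_fc <- max_ab / max_fc
  ggplot2::ggplot(long, ggplot2::aes(.data$label)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$abundance, fill = .data$tissue),
                      position = "dodge") +
    ggplot2::geom_point(
      data = d[!is.na(d$protein_fold_change), ],
      ggplot2::aes(y = .data$protein_fold_change * scale_fc),
      shape = 18, size = 3, color = "black"
    ) +
    ggplot2::geom_hline(yintercept = scale_fc, linetype = "dotted") +
    ggplot2::scale_y_continuous(
      name = "mean glycopeptide abundance",
      sec.axis = ggplot2::sec_axis(~. / scale_fc,
                                   name = "protein fold-change")
    ) +
    ggplot2::scale_fill_manual(values = c(tumor = "#2980b9",
                                          adjacent = "#c0392b")) +
    ggplot2::labs(x = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname plot_overlay
#' @param object,... autoplot arguments.
#' @export
autoplot.glyco_overlay <- function(object, ...) {
  plot_overlay(object)
}

#' NES bar chart of gene set enrichment results
#'
#' @param enrichment output of [preranked_gsea()].
#' @param top number of sets (by q) to show (default 20).
#' @param alpha fill threshold on q (default 0.05).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 20, alpha = 0.05) {
  d <- dplyr::slice_min(tibble::as_tibble(enrichment), .data$q, n = top,
                        with_ties = FALSE)
  d$set_id <- factor(d$set_id, levels = d$set_id[order(d$nes)])
  ggplot2::ggplot(d, ggplot2::aes(.data$nes, .data$set_id,
                                  fill = .data$q < alpha)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#27ae60",
                                          `FALSE` = "grey70"),
                               labels = c(`TRUE` = paste("q <", alpha),
                                          `FALSE` = "ns")) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
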