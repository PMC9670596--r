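#' Dot plot of tagged genes across identity groups
#'
#' Rows are the highlight group's upregulated tagged genes in chromosomal
#' order, columns are identity groups; point size maps absolute mean
#' normalized expression, colour maps Log2FC. MEG and PEG rows are drawn as
#' separate panels with disjoint colour maps (red/orange for MEGs, blues for
#' PEGs). A gene filtered out or unexpressed in a group is left blank rather
#' than drawn as a zero-size point.
#'
#' @param de a \code{de_table} (must carry mean_in, log2fc).
#' @param genes a \code{tagged_gene_list}.
#' @param highlight_group group whose upregulated tagged genes define the rows.
#' @param level analysis level; defaults to the level recorded in \code{de}.
#' @param q_cut upregulation cutoff, default 0.05.
#' @param out optional file path; the figure is written with
#'   \code{ggplot2::ggsave} when given.
#' @return a ggplot object (invisibly NULL with a warning when the selection
#'   is empty).
#' @export
dot_plot <- function(de, genes, highlight_group, level = NULL, q_cut = 0.05,
                     out = NULL) {
  if (is.null(level)) level <- attr(de, "level")
  up <- upregulated_set(de, highlight_group, level, q_cut = q_cut)
  sel <- genes[genes$gene_id %in% up, , drop = FALSE]
  if (!nrow(sel)) {
    warning("highlight group has no upregulated tagged genes; nothing to plot")
    return(invisible(NULL))
  }
  sel <- sel[order(sel$chromosome_order), , drop = FALSE]
  df <- de[de$gene %in% sel$gene_id, , drop = FALSE]
  df$origin <- sel$origin[match(df$gene, sel$gene_id)]
  df$gene <- factor(df$gene, levels = rev(sel$gene_id))
  df <- df[df$mean_in > 0, , drop = FALSE]       # blank, not zero-size
  panel <- function(sub, low, high) {
    if (!nrow(sub)) return(NULL)
    ggplot2::ggplot(sub, ggplot2::aes(x = .data$group, y = .data$gene,
                                      size = .data$mean_in,
                                      colour = .data$log2fc)) +
      ggplot2::geom_point() +
      ggplot2::scale_colour_gradient(low = low, high = high) +
      ggplot2::labs(x = NULL, y = NULL, size = "Mean expr.",
                    colour = "Log2FC",
                    title = unique(sub$origin)) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
  panels <- Filter(Negate(is.null),
                   list(panel(df[df$origin == "MEG", , drop = FALSE],
                              "orange", "red3"),
                        panel(df[df$origin == "PEG", , drop = FALSE],
                              "skyblue", "blue3")))
  p <- if (length(panels) == 2) {
    if (!requireNamespace("patchwork", quietly = TRUE))
      stop("the two-origin dot plot layout needs the 'patchwork' package")
    patchwork::wrap_plots(panels, ncol = 1)
  } else panels[[1]]
  if (!is.null(out)) ggplot2::ggsave(out, p, width = 8, height = 6)
  p
}

#' GSEA running-sum curve plot
#'
#' Draws the running enrichment curve for one group, tick marks at the
#' tagged-gene ranks, and a dashed line at the enrichment score (the curve's
#' maximum).
#'
#' @param result one row of a \code{gsea_result} (or the whole result plus
#'   \code{group}).
#' @param running_curve numeric running-sum curve; taken from the result's
#'   \code{"curves"} attribute when NULL.
#' @param group group to plot (needed when \code{result} has several rows).
#' @param out optional output path for \code{ggplot2::ggsave}.
#' @return a ggplot object.
#' @export
gsea_plot <- function(result, running_curve = NULL, group = NULL, out = NULL) {
  if (is.null(group)) group <- result$group[which(result$eligible)[1]]
  row <- result[result$group == group, , drop = FALSE]
  if (!nrow(row) || !isTRUE(row$eligible))
    stop("group is absent or not GSEA-eligible: ", group)
  if (is.null(running_curve)) running_curve <- attr(result, "curves")[[group]]
  n <- length(running_curve)
  df <- data.frame(rank = seq_len(n), score = running_curve)
  # hit positions: where the curve steps upward relative to the miss decrement
  steps <- diff(c(0, running_curve))
  hits <- which(steps > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = row$es, linetype = "dashed", colour = "red") +
    ggplot2::geom_rug(data = data.frame(rank = hits), sides = "b",
                      ggplot2::aes(x = .data$rank), inherit.aes = FALSE) +
    ggplot2::labs(x = "Rank by Log2FC", y = "Running enrichment score",
                  title = sprintf("%s (ES = %.3f, p = %.4g)",
                                  group, row$es, row$p_gsea)) +
    ggplot2::theme_bw()
  if (!is.null(out)) ggplot2::ggsave(out, p, width = 7, height = 4.5)
  p
}
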