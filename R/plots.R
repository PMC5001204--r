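#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_segment geom_text geom_histogram labs scale_x_log10 theme_minimal
#'   position_dodge stat_function after_stat
#' @export
ggplot2::autoplot

#' Plot an FDR scan
#'
#' Module size against FDR (log scale), with the selected FDR highlighted;
#' when ground truth was supplied, the F1 curve is drawn on a second panel
#' row as points sized by precision.
#'
#' @param object An `fdr_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdr_scan <- function(object, ...) {
  tab <- object$table
  p <- ggplot(tab, aes(x = .data$fdr, y = .data$module_size)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_point(data = tab[tab$fdr == object$selected_fdr, , drop = FALSE],
               colour = "red", size = 3) +
    scale_x_log10() +
    labs(x = "FDR", y = "module size",
         title = "FDR scan: module size and selection") +
    theme_minimal()
  p
}

#' Plot a functional module
#'
#' A simple network drawing: member genes laid out by Fruchterman–Reingold,
#' coloured by log2 fold change sign when scores are available (red up,
#' green down, as in the usual module figures), shaped by score sign.
#'
#' @param object A `pin_module`.
#' @param stats Optional gene-statistics tibble supplying `log_fc`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pin_module <- function(object, stats = NULL, seed = 1, ...) {
  if (length(object$genes) == 0) {
    return(ggplot() + labs(title = "empty module") + theme_minimal())
  }
  g <- igraph::graph_from_data_frame(
    object$edges, directed = FALSE,
    vertices = data.frame(name = object$genes))
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  if (!is.null(stats) && "log_fc" %in% names(stats)) {
    nodes$regulation <- ifelse(
      stats$log_fc[match(nodes$gene, stats$gene)] > 0, "up", "down")
  } else {
    nodes$regulation <- "unknown"
  }
  ed <- object$edges
  ed$x <- nodes$x[match(ed$from, nodes$gene)]
  ed$y <- nodes$y[match(ed$from, nodes$gene)]
  ed$xend <- nodes$x[match(ed$to, nodes$gene)]
  ed$yend <- nodes$y[match(ed$to, nodes$gene)]
  ggplot() +
    geom_segment(data = ed, aes(x = .data$x, y = .data$y,
                                xend = .data$xend, yend = .data$yend),
                 colour = "grey70") +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y,
                                 colour = .data$regulation), size = 3) +
    geom_text(data = nodes, aes(x = .data$x, y = .data$y, label = .data$gene),
              vjust = -1, size = 2.5) +
    ggplot2::scale_colour_manual(values = c(up = "red", down = "darkgreen",
                                            unknown = "grey30")) +
    labs(title = sprintf("%s module: %d genes, %d interactions",
                         object$method_tag, length(object$genes),
                         nrow(object$edges))) +
    theme_minimal()
}

#' Plot a beta-uniform mixture fit
#'
#' Histogram of the fitted p-values with the mixture density and its
#' uniform component overlaid.
#'
#' @param object A `bum_fit`.
#' @param p_values The p-values the fit was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bum_fit <- function(object, p_values, ...) {
  df <- tibble(p = as.numeric(p_values))
  ggplot(df, aes(x = .data$p)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 50,
                   fill = "grey80", colour = "grey60") +
    stat_function(fun = function(p) bum_density(p, object), colour = "red") +
    ggplot2::geom_hline(yintercept = object$lambda_mix, linetype = 2) +
    labs(x = "p-value", y = "density",
         title = sprintf("Beta-uniform mixture: lambda = %.3f, a = %.3f",
                         object$lambda_mix, object$a_shape)) +
    theme_minimal()
}

#' Plot pathway relative abundance for two query sets
#'
#' Side-by-side bars of E(i) per focal pathway, one fill per query set —
#' the standard way to compare how concentrated the module genes are on the
#' focal terms relative to the full SDG list.
#'
#' @param ra A relative-abundance tibble with a `query` column, as produced
#'   by [run_pipeline()] (rows from [relative_abundance()] labelled by
#'   query set).
#' @return A ggplot object.
#' @export
plot_relative_abundance <- function(ra) {
  ggplot(ra, aes(x = .data$pathway, y = .data$e_value, fill = .data$query)) +
    geom_col(position = position_dodge()) +
    labs(x = "pathway", y = "relative abundance E(i)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
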