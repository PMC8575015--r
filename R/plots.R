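#' @exportS3Method ggplot2::autoplot
autoplot.accuracy_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("C1", "C2", "C3"),
                              names_to = "criterion", values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$accuracy,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "panel size k", y = "accuracy",
                  title = "Panel accuracy vs panel size") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.panel_sweep <- function(object, criterion = "C1", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$lambda), y = factor(.data$mu),
                               fill = .data[[criterion]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(lambda), y = expression(mu),
                  fill = criterion,
                  title = "Accuracy over the parameter grid") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.specificity_table <- function(object, top = 20L, ...) {
  long <- tidy(object)
  keep <- names(sort(object$ss_gene, decreasing = TRUE))[seq_len(min(top, length(object$genes)))]
  ggplot2::ggplot(dplyr::filter(long, .data$gene_id %in% keep),
                  ggplot2::aes(x = .data$gene_id, y = .data$cell_type,
                               fill = .data$ss)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "gene", y = "cell type", fill = "ss",
                  title = "Specificity scores (top genes)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.celltype_network <- function(object, ...) {
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- tibble(name = igraph::V(object$graph)$name,
                  x = lay[, 1L], y = lay[, 2L])
  if (!is.null(object$modules)) {
    mem <- setNames(object$modules$module, object$modules$node)
    nodes$module <- factor(unname(mem[nodes$name]))
  } else {
    nodes$module <- factor(1)
  }
  seg <- dplyr::left_join(object$edges, nodes, by = c(from = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$module), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::labs(title = sprintf("Cell-type association network (Q = %.3f)",
                                  object$Q)) +
    ggplot2::theme_void()
}
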