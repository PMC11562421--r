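# ggplot2 visualizations for the fitted objects. Layout comes from igraph;
# drawing stays in ggplot2 so figures compose with the rest of a report.

network_plot_data <- function(weights, directed = TRUE, min_abs = 1e-10) {
  nm <- rownames(weights) %||% paste0("V", seq_len(nrow(weights)))
  g <- igraph::graph_from_adjacency_matrix(abs(weights) > min_abs,
                                           mode = if (directed) "directed" else "undirected")
  xy <- igraph::layout_in_circle(g)
  nodes <- tibble(node = nm, x = xy[, 1], y = xy[, 2])
  idx <- which(abs(weights) > min_abs & (directed | upper.tri(weights)), arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  edges <- tibble(
    from = nm[idx[, 1]], to = nm[idx[, 2]], weight = weights[idx],
    x = nodes$x[idx[, 1]], y = nodes$y[idx[, 1]],
    xend = nodes$x[idx[, 2]], yend = nodes$y[idx[, 2]]
  )
  list(nodes = nodes, edges = edges)
}

plot_network_gg <- function(weights, directed, title, communities = NULL) {
  pd <- network_plot_data(weights, directed = directed)
  pd$nodes$community <- if (is.null(communities)) "node" else as.character(communities)
  p <- ggplot2::ggplot()
  if (nrow(pd$edges)) {
    p <- p + ggplot2::geom_segment(
      data = pd$edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linewidth = abs(.data$weight), colour = .data$weight > 0),
      alpha = 0.7,
      arrow = if (directed) ggplot2::arrow(length = ggplot2::unit(0.18, "cm")) else NULL
    )
  }
  p +
    ggplot2::geom_point(data = pd$nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, fill = .data$community),
                        shape = 21, size = 9, colour = "grey20") +
    ggplot2::geom_text(data = pd$nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                       size = 2.6) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC", `FALSE` = "#B2182B"),
                                 guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(title = title, fill = NULL) +
    ggplot2::theme_void()
}

#' @export
autoplot.clpn <- function(object, ...) {
  plot_network_gg(object$weights, directed = TRUE,
                  title = sprintf("Cross-lagged network, waves %d → %d",
                                  object$wave_pair[1], object$wave_pair[2]),
                  communities = object$variables$community)
}

#' @export
autoplot.ggm <- function(object, communities = NULL, ...) {
  plot_network_gg(object$partial_corr, directed = FALSE,
                  title = sprintf("Contemporaneous network (EBIC γ = %g)",
                                  object$ebic_gamma),
                  communities = communities)
}

#' @export
autoplot.panel_gvar <- function(object,
                                network = c("temporal", "contemporaneous", "between"),
                                ...) {
  network <- match.arg(network)
  m <- switch(network,
              temporal = temporal_network(object),
              contemporaneous = contemporaneous_network(object),
              between = between_network(object))
  plot_network_gg(m, directed = network == "temporal",
                  title = sprintf("Panel GVAR %s network", network),
                  communities = object$variables$community)
}

#' @export
autoplot.stability_result <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = 1), alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_cor)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_cor)) +
    ggplot2::geom_hline(yintercept = object$cor_threshold, linetype = 2) +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "correlation with full-sample metric",
                  title = sprintf("Case-dropping stability (CS = %.2f)",
                                  object$cs_coefficient)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hierarchical_comparison <- function(object, ...) {
  tbl <- object$step2$coefficients
  tbl$term <- factor(tbl$term, levels = rev(tbl$term))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$std_estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$std_estimate - .data$se,
      xmax = .data$std_estimate + .data$se)) +
    ggplot2::labs(x = "standardized estimate ± SE", y = NULL,
                  title = sprintf("%s symptoms, wave %d (ΔR² = %.3f)",
                                  object$target, object$wave, object$delta_r2)) +
    ggplot2::theme_minimal()
}

#' Centrality dot plot
#' @param centrality A tibble from [strength_in_out()] or [bridge_strength()].
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality) {
  long <- tidyr::pivot_longer(centrality,
                              dplyr::where(is.numeric),
                              names_to = "metric", values_to = "value")
  long$node <- factor(long$node, levels = rev(unique(long$node)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$node)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
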