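#' Stacked duplication-class bars per species
#'
#' @param summary tibble from [duplication_summary()].
#' @return a ggplot object.
#' @export
plot_duplication_summary <- function(summary) {
  long <- tidyr::pivot_longer(summary,
                              cols = dplyr::all_of(duplication_classes()),
                              names_to = "class", values_to = "count")
  long$class <- factor(long$class, levels = duplication_classes())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes", fill = "duplication class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Length-variation retention curves
#'
#' One line per family; colored by cluster when a cluster assignment is
#' supplied.
#'
#' @param profiles long tibble from [length_variation_profile()].
#' @param clusters optional tibble from [cluster_length_profiles()].
#' @return a ggplot object.
#' @export
plot_length_variation <- function(profiles, clusters = NULL) {
  df <- profiles
  if (!is.null(clusters)) {
    df <- left_join(df, clusters, by = "family_id")
    df$cluster <- factor(df$cluster)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff,
                                        y = .data$retained_fraction,
                                        group = .data$family_id)) +
    ggplot2::labs(x = "length window half-width",
                  y = "retained fraction of members") +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    p + ggplot2::geom_line(ggplot2::aes(color = .data$cluster), alpha = 0.6)
  } else {
    p + ggplot2::geom_line(alpha = 0.6)
  }
}

#' Distribution of pairwise synonymous distances
#'
#' A histogram of defined Ks values; a bimodal shape separates ancient from
#' recent whole-genome duplications.
#'
#' @param ks_tbl tibble with a `ks` column (e.g. from
#'   [pairwise_ks_for_families()]).
#' @param binwidth histogram bin width.
#' @return a ggplot object.
#' @export
plot_ks_distribution <- function(ks_tbl, binwidth = 0.02) {
  df <- ks_tbl[!is.na(ks_tbl$ks), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = expression(K[s]), y = "gene pairs") +
    ggplot2::theme_minimal()
}

#' Plot a conservation profile
#'
#' @param object a `conservation_profile`.
#' @param ... unused.
#' @return a ggplot object of per-column conservation.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$column,
                                             y = .data$score)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_hline(yintercept = mean(object$column_scores),
                        linetype = 2, color = "firebrick") +
    ggplot2::labs(x = "alignment column", y = "conservation") +
    ggplot2::theme_minimal()
}

#' Plot a similarity network
#'
#' Force-directed layout with nodes colored by connected component.
#'
#' @param object a `similarity_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.similarity_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  comp <- igraph::components(g)$membership
  nodes$component <- factor(comp[nodes$id])
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$id)]
  edges$y <- nodes$y[match(edges$from, nodes$id)]
  edges$xend <- nodes$x[match(edges$to, nodes$id)]
  edges$yend <- nodes$y[match(edges$to, nodes$id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$component), size = 2) +
    ggplot2::theme_void() +
    ggplot2::guides(color = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
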