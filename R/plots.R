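# ggplot2 views of the main result types.

#' Boxplots of alpha indices by group
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param indices Index columns to show.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha, metadata,
                                 indices = intersect(c("richness", "chao1",
                                                       "shannon", "faith_pd"),
                                                     names(alpha))) {
  g <- group_labels(alpha, metadata, require_two = FALSE)
  long <- tidyr::pivot_longer(mutate(alpha, group = unname(g)),
                              all_of(indices),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1.5) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Stacked relative-abundance bars
#'
#' @param profile Abundance profile from [aggregate_rank()].
#' @return A ggplot object.
#' @export
plot_abundance_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, -"sample_id",
                              names_to = "taxon", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$abundance,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = attr(profile, "rank")) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.micronet_ordination <- function(object, metadata = NULL, ...) {
  co <- object$coordinates
  if (!is.null(metadata)) {
    co$group <- unname(group_labels(co, metadata, require_two = FALSE))
  }
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "Axis 1", y = "Axis 2", title = object$method)
  p <- if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
  if (!is.null(object$stress)) {
    p <- p + ggplot2::labs(subtitle = sprintf("stress = %.3f", object$stress))
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.micronet_rmt <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("ks_poisson", "ks_goe"),
                            names_to = "law", values_to = "ks")
  tr$law <- ifelse(tr$law == "ks_poisson", "Poisson", "GOE")
  ggplot2::ggplot(stats::na.omit(tr),
                  ggplot2::aes(x = .data$threshold, y = .data$ks,
                               colour = .data$law)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "Correlation threshold", y = "KS distance of NNSD",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.micronet_network <- function(object, partition = NULL, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(asv_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  if (!is.null(partition)) {
    nodes$cluster <- factor(partition$membership$cluster[
      match(nodes$asv_id, partition$membership$asv_id)])
  }
  e <- object$edges
  e$x <- nodes$x[match(e$from, nodes$asv_id)]
  e$y <- nodes$y[match(e$from, nodes$asv_id)]
  e$xend <- nodes$x[match(e$to, nodes$asv_id)]
  e$yend <- nodes$y[match(e$to, nodes$asv_id)]
  e$sign <- factor(ifelse(e$sign > 0, "positive", "negative"),
                   levels = c("positive", "negative"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$sign),
                          alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(positive = "darkgreen",
                                            negative = "red")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "correlation")
  if (!is.null(partition)) {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$cluster),
                            shape = 21, size = 2) +
      ggplot2::guides(fill = "none")
  } else {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(x = .data$x, y = .data$y),
                            size = 2)
  }
}
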