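# ggplot2 views of the three result types.

#' @describeIn build_pbcdm_network Plot a co-existence network: nodes sized
#'   by prevalence, edges coloured by sign, Fruchterman-Reingold layout
#'   (fixed internal seed, so a given network always draws the same).
#' @param object A `coexist_network`.
#' @param ... Unused.
#' @export
autoplot.coexist_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(42L, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1L], y = xy[, 2L])
  edges <- dplyr::left_join(
    dplyr::left_join(
      object$edges,
      dplyr::select(nodes, genus_a = "genus", xa = "x", ya = "y"),
      by = "genus_a"
    ),
    dplyr::select(nodes, genus_b = "genus", xb = "x", yb = "y"),
    by = "genus_b"
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   colour = .data$sign, linewidth = .data$weight),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$prevalence)
    ) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac", negative = "#b2182b")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::labs(title = paste0(object$method, " co-existence network"),
                  size = "prevalence", colour = "connection") +
    ggplot2::theme_void()
}

#' @describeIn shear_trajectory Plot the centralized eigenvector,
#'   betweenness and closeness scores along the shearing trajectory, with an
#'   optional vertical line at a selected stop step.
#' @param object A `shear_trajectory`.
#' @param stop_step Optional step to mark.
#' @export
autoplot.shear_trajectory <- function(object, stop_step = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("eig", "bet", "clo"),
                              names_to = "score", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$score), scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "shearing step (edges removed)", y = "centralized score")
  if (!is.null(stop_step)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(stop_step),
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' @describeIn attribute_trajectories Boxplots of the three network
#'   attributes across subsample sizes.
#' @param object A `stability_report`.
#' @export
autoplot.stability_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("n_nodes", "avg_links", "pn_ratio"),
                              names_to = "attribute", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$size), y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$attribute), scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "sample size", y = NULL,
                  title = paste0("Network stability (", object$method[1L], ")"))
}
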