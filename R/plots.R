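#' Plot a windowed track
#'
#' Window midpoints against the statistic, one panel per chromosome.
#'
#' @param object A windowed track tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.windowed_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = track_stat(object)) +
    ggplot2::theme_minimal()
}

#' Plot an rIBD track
#'
#' Z-scores along the chromosome with the calling threshold marked.
#'
#' @param object A [ribd_track()].
#' @param z_threshold Threshold line (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ribd_track <- function(object, z_threshold = 2, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$z)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = 2, colour = "red") +
    ggplot2::labs(x = "position (Mb)", y = "Z(rIBD)") +
    ggplot2::theme_minimal()
}

#' Plot an LD decay curve
#'
#' @param object An [ld_decay_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_decay_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df[!is.na(df$mean_r2), ],
                  ggplot2::aes(x = .data$mid / 1e3, y = .data$mean_r2)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "distance (kb)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' Plot a median-joining haplotype network
#'
#' Fruchterman-Reingold layout; node area scales with class count,
#' median vectors drawn as small open points.
#'
#' @param object A [median_joining_network()].
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplotype_network <- function(object, seed = 1, ...) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xy <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  e <- object$edges
  e$x <- nodes$x[match(e$from, nodes$id)]
  e$y <- nodes$y[match(e$from, nodes$id)]
  e$xend <- nodes$x[match(e$to, nodes$id)]
  e$yend <- nodes$y[match(e$to, nodes$id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e, ggplot2::aes(x = .data$x, y = .data$y,
                                                 xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = pmax(.data$count, 1),
                                     shape = .data$type)) +
    ggplot2::scale_shape_manual(values = c(observed = 16, median = 1)) +
    ggplot2::geom_text(data = nodes[nodes$type == "observed", ],
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
                       vjust = -1.2, size = 3) +
    ggplot2::guides(size = "none") +
    ggplot2::theme_void()
}
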