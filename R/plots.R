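# ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a demographic scenario as a step function
#'
#' @param object A `demographic_scenario`.
#' @param t_max Right edge of the time axis in generations (default: 1.5x the
#'   oldest epoch start, or 100 for a constant scenario).
#' @param ... Unused.
#' @return A ggplot: haploid effective size (log scale) against generations
#'   before present.
#' @export
autoplot.demographic_scenario <- function(object, t_max = NULL, ...) {
  ep <- object$epochs
  if (is.null(t_max)) t_max <- max(1.5 * max(ep$start), 100)
  df <- tibble::tibble(
    t = c(ep$start, t_max),
    size = c(ep$size, ep$size[nrow(ep)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$size)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present",
                  y = "haploid effective size",
                  title = object$id) +
    ggplot2::theme_minimal()
}

#' Plot ABC posteriors
#'
#' Weighted density of the adjusted draws per parameter with the posterior
#' mode and 90% HPD bounds.
#'
#' @param object An `abc_fit`.
#' @param ... Unused.
#' @return A ggplot faceted by parameter (free scales).
#' @export
autoplot.abc_fit <- function(object, ...) {
  s <- object$samples
  pars <- setdiff(names(s), ".weight")
  long <- tidyr::pivot_longer(s, dplyr::all_of(pars),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     weight = .data$.weight)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = object$posterior,
                        ggplot2::aes(xintercept = .data$mode)) +
    ggplot2::geom_vline(data = object$posterior,
                        ggplot2::aes(xintercept = .data$hpd_lower),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = object$posterior,
                        ggplot2::aes(xintercept = .data$hpd_upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = paste("scenario:", object$scenario)) +
    ggplot2::theme_minimal()
}

#' Plot a haplotype network
#'
#' Fruchterman-Reingold layout; node size scales with total frequency, fill
#' shows the share of the oldest layer; edges are labelled with mutational
#' steps.
#'
#' @param object A `haplotype_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplotype_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1)  # layout only; fixed for a stable picture
  xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
  nodes <- object$nodes
  cols <- layer_count_cols(nodes)
  oldest <- cols[length(cols)]
  nd <- tibble::tibble(haplotype = nodes$haplotype,
                       x = xy[, 1], y = xy[, 2],
                       n_total = nodes$n_total,
                       oldest_share = nodes[[oldest]] / nodes$n_total)
  ed <- dplyr::left_join(
    dplyr::left_join(object$edges,
                     dplyr::rename(nd[, c("haplotype", "x", "y")],
                                   from = "haplotype"), by = "from"),
    dplyr::rename(nd[, c("haplotype", "x", "y")],
                  to = "haplotype", xend = "x", yend = "y"), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_text(data = ed,
                       ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                    y = (.data$y + .data$yend) / 2,
                                    label = .data$steps), size = 3) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$n_total,
                                     fill = .data$oldest_share),
                        shape = 21) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(fill = sub("^n_", "share ", oldest), size = "n") +
    ggplot2::theme_void()
}
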