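# Node coordinates for drawing: leaves at x = 1..n in dendrogram order,
# each internal node centered over its children at y = merge height.
dendro_segments <- function(dendro) {
  n <- length(dendro$labels)
  members <- merge_members(dendro)
  leaf_order <- members[[n - 1L]]
  xpos <- numeric(n)
  xpos[leaf_order] <- seq_len(n)
  node_x <- numeric(n - 1L)
  node_y <- dendro$height
  segs <- vector("list", n - 1L)
  coord <- function(code) {
    if (code < 0) c(xpos[-code], 0) else c(node_x[code], node_y[code])
  }
  for (s in seq_len(n - 1L)) {
    a <- coord(dendro$merge[s, 1])
    b <- coord(dendro$merge[s, 2])
    node_x[s] <- (a[1] + b[1]) / 2
    h <- node_y[s]
    segs[[s]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h),
      yend = c(h, h, h)
    )
  }
  list(
    segments = dplyr::bind_rows(segs),
    leaves = tibble::tibble(
      country = dendro$labels[leaf_order],
      x = seq_len(n), y = 0
    )
  )
}

#' Plot a dendrogram
#'
#' @param object An `anx_dendrogram`.
#' @param fraction Optional height fraction at which to draw the cut line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot anx_dendrogram
#' @export
autoplot.anx_dendrogram <- function(object, fraction = NULL, ...) {
  geom <- dendro_segments(object)
  p <- ggplot2::ggplot(geom$segments) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::scale_x_continuous(
      breaks = geom$leaves$x, labels = geom$leaves$country
    ) +
    ggplot2::labs(x = NULL, y = "merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
  if (!is.null(fraction)) {
    p <- p + ggplot2::geom_hline(
      yintercept = fraction * max(object$height),
      linetype = "dashed", colour = "red"
    )
  }
  p
}

#' Plot per-country silhouette widths
#'
#' @param object An `anx_quality` report.
#' @param ... Unused.
#' @return A ggplot of silhouette widths grouped by cluster, with the mean
#'   silhouette as a dashed line.
#' @method autoplot anx_quality
#' @export
autoplot.anx_quality <- function(object, ...) {
  sil <- object$silhouette |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$sil_width)) |>
    dplyr::mutate(country = factor(.data$country, levels = .data$country))
  ggplot2::ggplot(sil, ggplot2::aes(
    x = .data$country, y = .data$sil_width, fill = factor(.data$cluster)
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$silhouette_mean, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "silhouette width", fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot the silhouette-vs-k profile of a k selection
#'
#' @param object An `anx_kselect` result.
#' @param ... Unused.
#' @return A ggplot marking both the silhouette maximizer and the
#'   dendrogram-cut candidate.
#' @method autoplot anx_kselect
#' @export
autoplot.anx_kselect <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$k, y = .data$silhouette_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    ggplot2::geom_vline(
      xintercept = object$candidate_k, linetype = "dotted", colour = "red"
    ) +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}
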