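# ggplot2 figures for the main result types. Display convention: T is
# shown as U (RNA alphabet) in base-composition plots; internally the
# alphabet stays DNA.

#' Stacked bar chart of category fractions across samples
#'
#' @param summaries A `composition_summary` or a list of them (one per
#'   sample).
#' @return A ggplot object.
#' @export
plot_category_fractions <- function(summaries) {
  if (inherits(summaries, "composition_summary")) {
    summaries <- list(summaries)
  }
  df <- dplyr::bind_rows(lapply(summaries, function(s)
    dplyr::mutate(s$category, sample = s$sample)))
  df$tier <- factor(df$tier, levels = TIER_ORDER,
                    labels = c("small RNA", "rRNA", "other RNA"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                   fill = .data$tier)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of annotated reads",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' Read-length histograms per group
#'
#' @param dist Output of [length_distribution()].
#' @return A ggplot object, faceted by group.
#' @export
plot_length_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "read length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}

#' 5'-base composition bars (T displayed as U)
#'
#' @param profile Output of [first_base_composition()].
#' @return A ggplot object.
#' @export
plot_base_composition <- function(profile) {
  profile$base <- factor(ifelse(profile$base == "T", "U", profile$base),
                         levels = c("A", "C", "G", "U"))
  ggplot2::ggplot(profile, ggplot2::aes(x = factor(.data$position),
                                        y = .data$fraction,
                                        fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "position (5' end = 1)", y = "fraction", fill = "base") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cumulative_coverage <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$rank,
                                             y = .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$target_fraction %||% 0.75,
                        linetype = "dashed") +
    ggplot2::labs(x = "abundance rank", y = "cumulative share") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pearson_hclust <- function(object, ...) {
  tree <- object$hclust
  n <- length(tree$order)
  # leaf x-positions in dendrogram order; internal nodes midway
  leaf_x <- setNames(seq_len(n), tree$order)
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  xpos <- function(id) if (id < 0) leaf_x[[as.character(-id)]] else node_x[id]
  hpos <- function(id) if (id < 0) 0 else node_h[id]
  segs <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    l <- tree$merge[i, 1]
    r <- tree$merge[i, 2]
    xl <- xpos(l)
    xr <- xpos(r)
    node_x[i] <- (xl + xr) / 2
    segs[[i]] <- tibble::tibble(
      x = c(xl, xl, xr), xend = c(xl, xr, xr),
      y = c(hpos(l), node_h[i], node_h[i]),
      yend = c(node_h[i], node_h[i], hpos(r))
    )
  }
  labels <- tibble::tibble(x = seq_len(n),
                           label = tree$labels[tree$order])
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = -0.02,
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::labs(x = NULL, y = "1 - Pearson correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
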