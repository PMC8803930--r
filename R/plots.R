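#' Volcano plot of a contrast result
#'
#' @param result Contrast-result tibble from [test_dpmp()] or
#'   [test_deg()].
#' @param label_top Label the `label_top` most significant features
#'   (0 disables labels).
#' @return A ggplot object.
#' @export
plot_volcano <- function(result, label_top = 0) {
  df <- dplyr::filter(result, !is.na(.data$log2fc))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p_value),
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    top <- df |>
      dplyr::filter(.data$significant) |>
      dplyr::slice_min(.data$p_value, n = label_top)
    p <- p + ggplot2::geom_text(
      data = top, ggplot2::aes(label = .data$feature_id),
      size = 2.5, vjust = -0.6, show.legend = FALSE
    )
  }
  p
}

#' DA-score heat map across models
#'
#' Pathway-by-model tile map of differential-abundance scores, the
#' display used to spot pathways consistently shifted with regenerative
#' capacity.
#'
#' @param scores DA score table from [da_score()] over several models.
#' @return A ggplot object.
#' @export
plot_da_heatmap <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(
    x = .data$model_id, y = .data$pathway_id, fill = .data$da_score
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      limits = c(-1, 1), name = "DA score"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Screen ranking plot
#'
#' @param ranked Output of [rank_screen()].
#' @return A ggplot object (relative proliferation per metabolite,
#'   best concentration, ranked).
#' @export
plot_screen_ranking <- function(ranked) {
  ggplot2::ggplot(ranked, ggplot2::aes(
    x = stats::reorder(.data$metabolite, -.data$rank),
    y = .data$relative_proliferation
  )) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative proliferation (treated / vehicle)") +
    ggplot2::theme_minimal()
}

#' @rdname plsda_ordination
#' @param object A `regen_plsda` object.
#' @param ... Unused.
#' @method autoplot regen_plsda
#' @export
autoplot.regen_plsda <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(
    x = .data$comp1, y = .data$comp2, colour = .data$group
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.9, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(
      x = sprintf("Component 1 (%.1f%% X var)", 100 * object$r2x[1L]),
      y = sprintf("Component 2 (%.1f%% X var)", 100 * object$r2x[2L]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname model_similarity
#' @param object A `model_tree` object.
#' @param ... Unused.
#' @method autoplot model_tree
#' @export
autoplot.model_tree <- function(object, ...) {
  h <- object$hclust
  # leaf positions in dendrogram order
  pos <- setNames(seq_along(h$order), h$order)
  xy <- matrix(NA_real_, nrow(h$merge), 2L)  # x, height per cluster
  segs <- vector("list", nrow(h$merge))
  coord <- function(id, step) {
    if (id < 0) c(pos[[as.character(-id)]], 0) else xy[id, ]
  }
  for (s in seq_len(nrow(h$merge))) {
    a <- coord(h$merge[s, 1L], s)
    b <- coord(h$merge[s, 2L], s)
    ht <- h$height[[s]]
    xy[s, ] <- c(mean(c(a[1L], b[1L])), ht)
    segs[[s]] <- tibble::tibble(
      x = c(a[1L], a[1L], b[1L]),
      xend = c(a[1L], b[1L], b[1L]),
      y = c(a[2L], ht, ht),
      yend = c(ht, ht, b[2L])
    )
  }
  labels <- tibble::tibble(
    x = seq_along(h$order),
    label = h$labels[h$order]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dplyr::bind_rows(segs),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = .data$x, y = 0, label = .data$label),
      angle = 90, hjust = 1.1, size = 3
    ) +
    ggplot2::scale_y_continuous(
      name = paste0(object$metric, " distance (", object$linkage,
                    " linkage)"),
      expand = ggplot2::expansion(mult = c(0.25, 0.05))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
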