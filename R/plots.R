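# autoplot() methods: quick diagnostic figures for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col geom_vline labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot a residue connectivity profile
#'
#' Average shortest-path length per residue ordinal; low values mark
#' well-connected residues. Residues named in `highlight` (e.g. catalytic
#' ones) are marked with vertical lines.
#'
#' @param object A `residue_profile`.
#' @param highlight Character vector of residue labels to mark.
#' @param normalized Plot the normalised values when present.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residue_profile
#' @export
autoplot.residue_profile <- function(object, highlight = NULL, normalized = FALSE, ...) {
  ycol <- if (normalized && "normalized_value" %in% names(object)) "normalized_value" else "value"
  df <- as_tibble(object)
  df <- dplyr::filter(df, is.finite(.data[[ycol]]))
  p <- ggplot(df, aes(x = .data$index, y = .data[[ycol]])) +
    geom_line(colour = "grey40") +
    geom_point(size = 0.8) +
    labs(x = "residue ordinal",
         y = if (ycol == "value") "average shortest-path length" else
           "normalised average shortest-path length",
         title = sprintf("Residue connectivity profile (%s network)",
                         attr(object, "semantics") %||% "unknown")) +
    theme_minimal()
  if (!is.null(highlight)) {
    marks <- dplyr::filter(df, .data$label %in% highlight)
    p <- p + geom_vline(data = marks, aes(xintercept = .data$index),
                        linetype = "dashed", colour = "firebrick") +
      geom_point(data = marks, colour = "firebrick", size = 2)
  }
  p
}

#' Heatmap of a pair energy matrix
#' @param object A [pair_energy_matrix()].
#' @param ... Unused.
#' @return A ggplot object (tile heatmap of mean |E|, kcal/mol).
#' @method autoplot pair_energy_matrix
#' @export
autoplot.pair_energy_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$energy <- m[cbind(df$i, df$j)]
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$energy)) +
    geom_tile() +
    scale_fill_viridis_c(name = "mean |E|\n(kcal/mol)") +
    labs(x = "residue ordinal", y = "residue ordinal",
         title = "Mean absolute residue interaction energy") +
    theme_minimal()
}

#' Plot an aligned profile comparison
#'
#' Absolute normalised profile difference per aligned column; gap columns
#' (residues without a partner) appear as breaks in the series.
#'
#' @param object An `aligned_comparison`.
#' @param highlight Residue labels (of structure A) to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aligned_comparison
#' @export
autoplot.aligned_comparison <- function(object, highlight = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(dplyr::filter(df, !is.na(.data$diff)),
              aes(x = .data$column, y = .data$diff)) +
    geom_col(width = 1, fill = "grey35") +
    labs(x = "aligned residue index", y = "|normalised profile difference|",
         title = "Cross-structure connectivity difference") +
    theme_minimal()
  if (!is.null(highlight)) {
    marks <- dplyr::filter(df, .data$label_a %in% highlight)
    p <- p + geom_vline(data = marks, aes(xintercept = .data$column),
                        linetype = "dashed", colour = "firebrick")
  }
  p
}
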