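#' Heatmap of pairwise combinational degrees
#'
#' Tiles the normalized CD of every formula pair; the diagonal shows the
#' self-pair score (a length effect: (L + 1)/2 over the scale, clamped at 1).
#'
#' @param formulae Formula table.
#' @param scale CD normalization constant.
#' @return A ggplot object.
#' @export
plot_cd_heatmap <- function(formulae, scale = 7.5) {
  pairs <- cd_pairs(formulae, scale)
  self <- tibble(
    f1 = formulae$name, f2 = formulae$name,
    cd = suppressWarnings(
      normalize_cd((lengths(formulae$herbs) + 1) / 2, scale))
  )
  full <- dplyr::bind_rows(
    pairs[, c("f1", "f2", "cd")],
    dplyr::rename(pairs[, c("f1", "f2", "cd")], f1 = "f2", f2 = "f1"),
    self
  )
  ggplot2::ggplot(full, ggplot2::aes(x = .data$f1, y = .data$f2,
                                     fill = .data$cd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "CD") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stacked component view of herb attribute similarities
#'
#' Shows, for each herb pair of an [as_pairs()] result, the five components
#' stacked to their AS total, with the high-similarity threshold marked.
#'
#' @param as_tbl Output of [as_pairs()] or row-bound [as_score()] calls.
#' @param threshold Threshold line (default 3).
#' @return A ggplot object.
#' @export
plot_as_components <- function(as_tbl, threshold = 3) {
  long <- tidyr::pivot_longer(
    as_tbl,
    cols = c("a_nature", "b_taste", "c_channel", "d_function", "e_indication"),
    names_to = "component", values_to = "value"
  )
  long$pair <- paste(long$herb1, "/", long$herb2)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "attribute similarity (AS)") +
    ggplot2::theme_minimal()
}

#' @rdname overrepresentation
#' @param object A `tcm_ora` tibble (for `autoplot`).
#' @export
autoplot.tcm_ora <- function(object, ...) {
  df <- as_tibble(object)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$pathway,
                                   size = .data$overlap)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](italic(p))), y = NULL,
                  size = "overlap") +
    ggplot2::theme_minimal()
}
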