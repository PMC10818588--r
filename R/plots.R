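#' Heatmap of a quantitative matrix
#'
#' Residues (table order, Ala at the top) against core positions, with a
#' diverging fill: positive cells mark preferred residues, negative cells
#' non-preferred ones — the quantitative counterpart of a sequence logo.
#'
#' @param object A `peplogo_qm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peplogo_qm <- function(object, ...) {
  df <- tidy(object)
  df$residue <- factor(df$residue, levels = rev(AA_THREE))
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-lim, lim)) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(df$position)),
                                labels = paste0("p", seq_len(max(df$position))),
                                expand = c(0, 0)) +
    ggplot2::labs(
      title = sprintf("%s %s logo model (N = %s)",
                      attr(object, "allele") %||% "", attr(object, "label") %||% "",
                      attr(object, "n_peptides") %||% "?"),
      x = "core position", y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}

#' Confidence-ratio breakdown of an evaluation
#'
#' Percentage of each confusion-matrix cell (TP/FN/TN/FP) per confidence bin.
#' Misclassifications concentrate in the `uncertain` bin (ratio strictly
#' between −1 and +1).
#'
#' @param object A `peplogo_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peplogo_eval <- function(object, ...) {
  bb <- ratio_bin_table(object$scores)
  ggplot2::ggplot(bb, ggplot2::aes(x = .data$bin, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "confidence-ratio bin", y = "% of cell",
                  title = sprintf("%s: prediction confidence by outcome",
                                  object$allele %||% "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
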