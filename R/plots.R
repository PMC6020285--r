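#' Volcano plot of a differential-expression table
#'
#' Linear fold change (log-scaled x axis) against -log10 FDR, with the
#' significance gate drawn and significant genes highlighted.
#'
#' @param object An `shh_de` table.
#' @param alpha FDR gate drawn on the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shh_de
#' @export
autoplot.shh_de <- function(object, alpha = 0.01, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      significant = .data$fdr < alpha & .data$direction != "flat")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc, y = -log10(.data$fdr),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "black")) +
    ggplot2::labs(x = paste0("fold change (", attr(object, "comparison"), ")"),
                  y = expression(-log[10] ~ "FDR"),
                  colour = paste0("FDR < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Concordance scatter of common genes
#'
#' In vitro fold change against oriented in vivo fold change, both on log2
#' axes, coloured by concordance class. Concordant-positive genes fall in the
#' upper-right quadrant, concordant-negative in the lower-left.
#'
#' @param object An `shh_concordance` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shh_concordance
#' @export
autoplot.shh_concordance <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fc_vivo, y = .data$fc_vitro,
                               colour = .data$klass)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_colour_manual(values = c(concordant_positive = "#e6b800",
                                            concordant_negative = "#2166ac",
                                            discordant = "grey60")) +
    ggplot2::labs(x = "in vivo fold change (Veh/Cyc)",
                  y = "in vitro fold change (SHH/Veh)", colour = NULL) +
    ggplot2::theme_minimal()
}
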