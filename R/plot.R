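#' Volcano plot of the region screen
#'
#' Delta-beta against -log10 BH-adjusted p for every tested region, selected
#' regions highlighted. Requires ggplot2.
#'
#' @param records Annotated records from [screen_regions()].
#' @param params Screen parameters (threshold guide lines).
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, params = screen_params()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_volcano requires the ggplot2 package", call. = FALSE)
  }
  vd <- volcano_data(records)
  ggplot2::ggplot(vd, ggplot2::aes(x = .data$delta_beta,
                                   y = .data$neg_log10_adj_p,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-params$delta_cut, params$delta_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(params$fdr_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * beta ~ "(tumor - normal)"),
                  y = expression(-log[10] ~ "adjusted" ~ italic(p)),
                  colour = "selected") +
    ggplot2::theme_minimal()
}
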