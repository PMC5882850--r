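# ggplot2 views of the main result types.

#' @export
autoplot.hydropathy_profile <- function(object, threshold = 1.6, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$hydropathy)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "residue", y = "mean hydropathy",
      title = sprintf("Kyte-Doolittle hydropathy (window %d)",
                      attr(object, "window"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.topology_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
      fill = .data$compartment
    )) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = 0.5, label = .data$label
    ), size = 2.6, angle = 90) +
    ggplot2::scale_fill_manual(values = c(
      membrane = "#e0c068", intracellular = "#8db4d9", extracellular = "#c5e0b4"
    )) +
    ggplot2::labs(x = "residue", y = NULL,
                  title = paste("7TM topology:", attr(object, "seq_id"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.chimera_design <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
      fill = .data$source
    )) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = 0.5, label = .data$label
    ), size = 2.6, angle = 90) +
    ggplot2::scale_fill_manual(values = c(backbone = "#4472c4", target = "#d95f5f")) +
    ggplot2::labs(
      x = "residue", y = NULL, fill = "source",
      title = sprintf("chimera: %s backbone + %s intracellular parts",
                      attr(object, "backbone_id"), attr(object, "target_id"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot relative-expression fold changes
#'
#' @param data Output of [relative_expression()].
#' @return A ggplot object (log2 fold-change bars per sample).
#' @export
plot_fold_changes <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$sample, y = .data$fold_change)) +
    ggplot2::geom_col(fill = "#4472c4") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "fold change (2^-ddCt, log2 scale)") +
    ggplot2::theme_minimal()
}
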