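# Bar-chart renderings of TFA results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a TFA report
#'
#' Gibbs energy of reaction per glycolytic reaction; negative bars are
#' feasible.
#'
#' @param object a `tfa_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tfa_report
#' @export
autoplot.tfa_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste0(df$number, " ", df$reaction_id)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$number),
                                   y = .data$dRg, fill = .data$feasible)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey35", `FALSE` = "firebrick"),
                               na.value = "grey80", name = "feasible") +
    ggplot2::labs(x = NULL, y = expression(Delta^R * g ~ "(kJ/mol)"),
                  title = paste0("TFA - conditions ", attr(object, "conditions"),
                                 ", ", attr(object, "mode"), " mode, ",
                                 attr(object, "T"), " K")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Paired bar chart of activity- vs concentration-based dRg
#'
#' @param object a `tfa_comparison` from [compare_modes()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tfa_comparison
#' @export
autoplot.tfa_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste0(df$number, " ", df$reaction_id)
  long <- tidyr::pivot_longer(df, cols = c("dRg", "dRg_c"),
                              names_to = "approach", values_to = "value")
  long$approach <- ifelse(long$approach == "dRg", "activity-based",
                          "concentration-based")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$label, .data$number),
                                     y = .data$value, fill = .data$approach)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c("activity-based" = "grey25",
                                          "concentration-based" = "grey65")) +
    ggplot2::labs(x = NULL, y = expression(Delta^R * g ~ "(kJ/mol)"),
                  fill = NULL,
                  title = paste0("Activity- vs concentration-based TFA (conditions ",
                                 attr(object, "conditions"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
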