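## ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Quantile-quantile plot of a recurrence batch
#'
#' Observed versus expected -log10 combined p-values under the uniform
#' null, with the BH-significant regions highlighted.
#'
#' @param object a `recurrence_result`.
#' @param q_max highlight threshold.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot recurrence_result
#' @export
autoplot.recurrence_result <- function(object, q_max = 0.05, ...) {
  d <- object |>
    filter(!is.na(.data$p_combined)) |>
    arrange(.data$p_combined) |>
    mutate(expected = -log10(stats::ppoints(n())),
           observed = -log10(.data$p_combined),
           significant = .data$q < q_max)
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed,
                                  colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  colour = paste0("Q < ", q_max)) +
    ggplot2::theme_minimal()
}

#' 96-channel mutation spectrum barplot
#'
#' @param object a `spectrum96`.
#' @param ... unused.
#' @return a ggplot faceted by substitution type.
#' @method autoplot spectrum96
#' @export
autoplot.spectrum96 <- function(object, ...) {
  ch <- sbs_channels()
  d <- ch |>
    mutate(count = as.integer(object[ch$channel]),
           substitution = paste0(.data$ref, ">", .data$alt),
           context = paste0(.data$five, ".", .data$three))
  ggplot2::ggplot(d, ggplot2::aes(.data$context, .data$count,
                                  fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~substitution, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "trinucleotide context", y = "mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}

#' Volcano plot of expression-effect tests
#'
#' @param object a `de_result`.
#' @param ... unused.
#' @return a ggplot of log2 fold change against -log10 p, candidates
#'   highlighted.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  d <- filter(object, !is.na(.data$p))
  ggplot2::ggplot(d, ggplot2::aes(log2(.data$fold_change), -log10(.data$p),
                                  colour = .data$candidate)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ fold ~ change),
                  y = expression(-log[10](p)), colour = "candidate") +
    ggplot2::theme_minimal()
}
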