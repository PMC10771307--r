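#' Forest plot of a disproportionality screen
#'
#' Shows, for one scope, the reporting odds ratios and 95% confidence
#' intervals of the most-reported drugs on a log axis, coloured by signal
#' classification, with the null line at ROR = 1.
#'
#' @param object a `ror_screen` from [detect_all_signals()].
#' @param scope scope to display (default: the SMQ level).
#' @param top_n show the `top_n` drugs by case count.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ror_screen <- function(object, scope = NULL, top_n = 20, ...) {
  scope <- scope %||% attr(object, "smq_name")
  scope_key <- fold_name(scope)
  df <- tibble::as_tibble(object) |>
    dplyr::filter(fold_name(.data$scope) == scope_key) |>
    dplyr::arrange(dplyr::desc(.data$n_cases)) |>
    utils::head(top_n) |>
    dplyr::mutate(drug = stats::reorder(.data$drug, .data$ror))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$drug,
                                   colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(positive = "#c0392b", negative = "#2c3e50")) +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "Signal", title = scope)
}

#' Bar chart of the positive-signal-count distribution
#'
#' @param x a `positive_signal_summary` from [count_positive_signals()].
#' @return a ggplot object.
#' @export
plot_signal_distribution <- function(x) {
  stopifnot(inherits(x, "positive_signal_summary"))
  ggplot2::ggplot(x$distribution,
                  ggplot2::aes(x = factor(.data$n_positive, levels = 7:0),
                               y = .data$n_drugs)) +
    ggplot2::geom_col(fill = "#2980b9") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)",
                                                    .data$n_drugs, .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Number of positive signals (of 7 scopes)",
                  y = "Number of drugs")
}

#' Bar chart of a ranked reporting-proportion table
#'
#' @param x a ranked tibble from [reporting_proportions()] or
#'   [top_reported()].
#' @return a ggplot object.
#' @export
plot_reporting_proportions <- function(x) {
  stopifnot(all(c("name", "proportion") %in% names(x)))
  df <- dplyr::mutate(x, name = stats::reorder(.data$name, .data$proportion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proportion, y = .data$name)) +
    ggplot2::geom_col(fill = "#27ae60") +
    ggplot2::labs(x = "Reporting proportion (%)", y = NULL)
}

#' Bar chart of one report-characteristics panel
#'
#' @param chars the list returned by [summarize_characteristics()].
#' @param panel which panel to draw (`"year"`, `"submitter"`,
#'   `"country"`, `"sex"`, `"age"`, `"outcome"`, `"pt"`).
#' @return a ggplot object.
#' @export
plot_characteristics <- function(chars, panel = "year") {
  stopifnot(panel %in% names(chars))
  df <- chars[[panel]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#8e44ad") +
    ggplot2::labs(x = NULL, y = "Reports", title = panel) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
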