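#' Plot SV type composition
#'
#' Bar chart of per-platform SV type proportions, the standard view for
#' contrasting what each sequencing method detects.
#'
#' @param composition Tibble from [type_composition()], optionally
#'   row-bound across callsets with a `method` column.
#' @return A ggplot.
#' @export
plot_type_composition <- function(composition) {
  if (!"method" %in% names(composition)) composition$method <- "callset"
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$svtype, y = .data$proportion,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "SV type", y = "Proportion of calls", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a filter-cascade trace
#'
#' @param trace Trace tibble from [apply_filter_cascade()].
#' @return A ggplot of removals per rule, in application order.
#' @export
plot_filter_trace <- function(trace) {
  trace$rule <- factor(trace$rule, levels = trace$rule)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$rule, y = .data$removed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Filter rule (application order)", y = "Variants removed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
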