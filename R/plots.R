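# ggplot2 views of trajectories and experiment tables.

#' Plot a DCJ trajectory
#'
#' One panel per recorded statistic against the step count `k`.
#'
#' @param object A `dcj_trajectory` from [simulate_dcj()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcj_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"k",
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y") +
    ggplot2::labs(x = "DCJ steps k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot estimated against true DCJ counts
#'
#' Draws each estimator's (or coding choice's) estimates against the true
#' step count, with the diagonal as reference.  Saturated (infinite)
#' estimates are dropped.
#'
#' @param results A long table from [run_estimator_comparison()] (column
#'   `estimator`) or [run_seq_length_sweep()] (column `method`).
#' @return A ggplot object.
#' @export
plot_estimator_comparison <- function(results) {
  series <- if ("estimator" %in% names(results)) "estimator" else "method"
  df <- dplyr::filter(results, is.finite(.data$k_hat))
  if (length(unique(df$seed)) > 1) {
    df <- dplyr::summarise(
      dplyr::group_by(df, .data[[series]], .data$k),
      k_hat = median(.data$k_hat), .groups = "drop")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$k_hat,
                                   color = .data[[series]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "true number of DCJs k", y = "estimated k",
                  color = NULL) +
    ggplot2::theme_minimal()
}
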