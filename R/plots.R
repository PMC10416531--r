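#' Plot observed betas by standard level
#'
#' Boxplots of observed methylation per expected standard level, with the
#' expected values as reference marks — the standard figure for a
#' repeatability series. The widening of boxes at intermediate levels
#' visualises the variance peak expected from binomial counting noise.
#'
#' @param betas Long beta tibble.
#' @param samples Metadata with `sample_id`, `expected_beta`.
#' @return A ggplot object.
#' @export
plot_standard_betas <- function(betas, samples) {
  cells <- betas |>
    inner_join(select(samples, "sample_id", "expected_beta"), by = "sample_id") |>
    filter(!is.na(.data$beta))
  ggplot(cells, aes(factor(.data$expected_beta), .data$beta)) +
    geom_boxplot(outlier.size = 0.4, fill = "grey90") +
    geom_point(aes(y = .data$expected_beta), colour = "red3", shape = 95,
               size = 6) +
    labs(x = "expected methylation level", y = "observed beta") +
    theme_minimal()
}

#' Heatmap of a cross-method correlation matrix
#'
#' @param mat Symmetric correlation matrix (e.g.
#'   `method_correlation()$spearman` or [clock_cross_correlation()]).
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(mat) {
  df <- as_tibble(mat, rownames = "row") |>
    pivot_longer(-"row", names_to = "col", values_to = "r")
  ggplot(df, aes(.data$col, .data$row, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0.5, limits = c(min(df$r, 0), 1)) +
    labs(x = NULL, y = NULL, fill = "R") +
    theme_minimal()
}

#' Predicted versus chronological age
#'
#' Scatter of clock outputs against chronological age with the identity
#' line; calibrated values, when present, are shown alongside the raw ones.
#'
#' @param clocks Clock-output tibble (`sample_id`, `clock`, `value`,
#'   optionally `value_calibrated`).
#' @param ages Tibble `sample_id`, `age`.
#' @param which_clocks Clock names to show; default all with year units as
#'   present in the table.
#' @return A ggplot object.
#' @export
plot_age_prediction <- function(clocks, ages, which_clocks = NULL) {
  df <- clocks |>
    left_join(select(ages, "sample_id", "age"), by = "sample_id") |>
    filter(!is.na(.data$age))
  if (!is.null(which_clocks)) df <- filter(df, .data$clock %in% which_clocks)
  long <- df |>
    pivot_longer(any_of(c("value", "value_calibrated")),
                 names_to = "stage", values_to = "prediction") |>
    mutate(stage = ifelse(.data$stage == "value", "raw", "calibrated"))
  ggplot(long, aes(.data$age, .data$prediction, colour = .data$stage)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point() +
    facet_wrap(~clock, scales = "free_y") +
    labs(x = "chronological age (years)", y = "predicted value") +
    theme_minimal()
}
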