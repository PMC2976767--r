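#' Plot a support-bin table
#'
#' Bar chart of the six cumulative support categories.
#'
#' @param bins A `support_bins` tibble (one or more rows; an optional
#'   `label` column distinguishes rows).
#' @return A ggplot object.
#' @export
plot_support_bins <- function(bins) {
  df <- tibble::as_tibble(bins)
  if (!"label" %in% names(df)) df$label <- paste0("tree", seq_len(nrow(df)))
  long <- tidyr::pivot_longer(df, c("lt50", "ge50", "b50_70", "ge70",
                                    "b70_85", "ge85"),
                              names_to = "bin", values_to = "pct")
  long$bin <- factor(long$bin, levels = c("lt50", "ge50", "b50_70", "ge70",
                                          "b70_85", "ge85"),
                     labels = c("<50", ">50", "50-70", ">70", "70-85", ">85"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$pct,
                                     fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "support category (%)", y = "% of nodes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.support_bins <- function(object, ...) plot_support_bins(object)

#' Plot a recovery table
#'
#' Percent recovery per marker (and marker union) at each taxonomic level.
#'
#' @param recovery A `recovery_table` tibble.
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery) {
  df <- tibble::as_tibble(recovery)
  df$level <- factor(df$level, levels = c("sample", "species", "genus",
                                          "family", "order"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$pct,
                                   group = .data$column,
                                   colour = .data$column)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "% recovered", colour = "marker") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.recovery_table <- function(object, ...) plot_recovery(object)
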