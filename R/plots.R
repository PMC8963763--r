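# ggplot2 visualisations: Z-score heatmap, differential-call overview and
# Kaplan-Meier step curves.

#' Heatmap of Z-scored methylation across samples
#'
#' Tile heatmap of per-probe Z-scores with samples ordered by hierarchical
#' clustering (Euclidean distance), the standard view for inspecting
#' whether differential probes separate responder groups. Red marks high
#' relative methylation signal, blue low.
#'
#' @param z Long tibble with a `z` column from [zscore_transform()];
#'   typically restricted to significant probes.
#' @param labels Optional tibble (`sample_id`, `group`) used to annotate
#'   the x axis.
#' @param linkage Linkage for the sample ordering (see
#'   [cluster_samples()]).
#' @return A ggplot object.
#' @export
plot_methylation_heatmap <- function(z, labels = NULL, linkage = "average") {
  cl <- cluster_samples(z, labels, linkage = linkage)
  ord <- cl$leaf_order
  df <- dplyr::mutate(tibble::as_tibble(z),
                      sample_id = factor(.data$sample_id, levels = ord))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                        y = .data$probe_id,
                                        fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-2, 2),
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(labels)) {
    grp <- labels$group[match(ord, labels$sample_id)]
    p <- p + ggplot2::scale_x_discrete(labels = paste0(ord, " (", grp, ")"))
  }
  p
}

# minimal squish so we avoid a hard scales dependency
scales_squish <- function(x, range = c(-2, 2)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Differential-call overview plot
#'
#' Mean BW difference (TR minus CR) against -log10 p for every probe,
#' coloured by methylation direction.
#'
#' @param records Probe-level tibble from [call_dmrs()] (ideally with
#'   `keep_all = TRUE`).
#' @param alpha Significance level drawn as a horizontal guide.
#' @return A ggplot object.
#' @export
plot_dmr_overview <- function(records, alpha = attr(records, "alpha") %||% 0.01) {
  df <- tibble::as_tibble(records)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diff,
                                   y = -log10(.data$p),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(hyper = "#B2182B",
                                            hypo = "#2166AC")) +
    ggplot2::labs(x = "mean BW difference (TR - CR)",
                  y = expression(-log[10] ~ p),
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_km Kaplan-Meier curve for a single fitted group.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$steps[, c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier comparison plot
#'
#' Step curves for the two methylation-status groups of a
#' [compare_survival()] result, annotated with the log-rank p-value.
#'
#' @param comparison A `survival_comparison`.
#' @param object,... For the `autoplot` methods.
#' @return A ggplot object.
#' @export
plot_km <- function(comparison) {
  stopifnot(inherits(comparison, "survival_comparison"))
  df <- tidy.survival_comparison(comparison) |>
    dplyr::group_by(.data$status) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1), .x[, c("time", "survival")]
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$status)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = paste0(comparison$gene, " (", toupper(comparison$endpoint), ")"),
      subtitle = sprintf("log-rank p = %.2g", comparison$logrank$p_value),
      x = "months", y = "survival probability", colour = "MSP status"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_km `autoplot` method for `survival_comparison`.
#' @export
autoplot.survival_comparison <- function(object, ...) plot_km(object)
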