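# ggplot2 displays for the main result types.

#' @export
autoplot.bloom_alpha <- function(object, index = c("shannon", "sobs", "pielou"), ...) {
  index <- match.arg(index)
  if (!"region" %in% names(object)) {
    abort("alpha result lacks a `region` column; pass metadata to alpha_diversity()")
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$region, y = .data[[index]], fill = .data$region
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15, size = 1.5, alpha = 0.6) +
    ggplot2::labs(
      x = NULL,
      y = switch(index,
        shannon = "Shannon index (nats)",
        sobs = "Observed richness (Sobs)",
        pielou = "Pielou's evenness"
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.bloom_pcoa <- function(object, metadata = NULL, colour = "region", ...) {
  df <- object$scores
  if (!is.null(metadata)) {
    df <- left_join(df, metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  if (colour %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PCoA1 (%.1f%%)", object$percent_explained[1]),
      y = sprintf("PCoA2 (%.1f%%)", object$percent_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bloom_forward <- function(object, ...) {
  sel <- object$selection
  if (nrow(sel) == 0) abort("no variables were selected; nothing to plot")
  sel$variable <- factor(sel$variable, levels = sel$variable)
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$variable, y = .data$adj_r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      yintercept = object$full_adj_r2,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "selection order", y = expression("cumulative adjusted" ~ R^2)
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot comparing two regions' network topology
#'
#' @param comparison Output of [compare_regions()].
#' @return A ggplot object.
#' @export
plot_network_comparison <- function(comparison) {
  df <- comparison %>%
    filter(.data$metric != "multi_module") %>%
    tidyr::pivot_longer(c("br", "nr"), names_to = "region", values_to = "value") %>%
    mutate(region = toupper(.data$region))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$value, y = .data$metric, colour = .data$region
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "value (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
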