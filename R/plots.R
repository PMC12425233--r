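#' Plot chromosomal proportions of regulated genes
#'
#' Bars of the proportion of down- and up-regulated genes per chromosome
#' class with significance stars from the Yates chi-square tests.
#'
#' @param enrichment Output of [run_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$chromosome_class, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$autosome_regulated /
                                       .data$autosome_total),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.3) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = NULL, y = "proportion of annotated genes",
                  caption = "dashed line: autosomal proportion") +
    ggplot2::theme_minimal()
}

#' Plot X:AA ratios across stages
#'
#' Per-replicate ratios as points with the pooled estimate as a bar,
#' faceted by method and threshold. A meiotic dip of the X (or neo-X)
#' series is the MSCI signature.
#'
#' @param xaa_table Output of [xaa_stage_table()].
#' @return A ggplot object.
#' @export
plot_xaa <- function(xaa_table) {
  dat <- xaa_table %>% mutate(stage = factor(.data$stage, levels = STAGES))
  ggplot2::ggplot(dat %>% filter(.data$replicate != "pooled"),
                  ggplot2::aes(x = .data$stage, y = .data$ratio,
                               colour = .data$numerator_class)) +
    ggplot2::geom_boxplot(outlier.shape = NA, position = "dodge") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.75), size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_grid(method ~ threshold,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "X:AA ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot age-by-location stage trajectories
#'
#' Mean log2 expression with SEM error bars per stage, coloured by age
#' group and faceted by chromosome class.
#'
#' @param trajectories Output of [stage_trajectories()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$stage, y = .data$mean,
                               colour = .data$age_group,
                               group = .data$age_group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::facet_wrap(~chromosome_class) +
    ggplot2::labs(x = NULL, y = "mean log2 normalized expression",
                  colour = "gene age") +
    ggplot2::theme_minimal()
}

#' @describeIn kmeans_profiles Centroid stage profiles per cluster.
#' @param object An `msci_clusters` object.
#' @method autoplot msci_clusters
#' @export
autoplot.msci_clusters <- function(object, ...) {
  cent <- as_tibble(object$centroids) %>%
    mutate(cluster = factor(dplyr::row_number())) %>%
    tidyr::pivot_longer(-"cluster", names_to = "stage", values_to = "z") %>%
    mutate(stage = factor(.data$stage, levels = STAGES))
  ggplot2::ggplot(cent, ggplot2::aes(x = .data$stage, y = .data$z,
                                     group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "centroid Z-score") +
    ggplot2::theme_minimal()
}

#' @describeIn de_contrast MA-style plot of the contrast, coloured by
#'   class.
#' @param object An `msci_de` object.
#' @method autoplot msci_de
#' @export
autoplot.msci_de <- function(object, ...) {
  dat <- object$results %>% filter(.data$tested)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$base_mean, y = .data$log2fc,
                                    colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(down = "steelblue", up = "firebrick",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "mean normalized count",
                  y = paste0("log2 FC (", object$numerator, " / ",
                             object$denominator, ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
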