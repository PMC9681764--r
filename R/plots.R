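#' Plot daily habitability windows
#'
#' Line plot of daily wet and wet + light hours over the record, faceted by
#' site and sensor position.
#'
#' @param hab_days A habitability tibble from [habitability_days()] or
#'   [habitability_from_readings()].
#'
#' @return A ggplot object.
#' @export
plot_habitability <- function(hab_days) {
  long <- hab_days |>
    tidyr::pivot_longer(c("wet_hours", "wetlight_hours"),
                        names_to = "condition", values_to = "hours") |>
    mutate(condition = dplyr::recode(.data$condition,
      wet_hours = "wet", wetlight_hours = "wet + light"
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$hours,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(position ~ site) +
    ggplot2::scale_colour_manual(values = c("wet" = "#2166ac",
                                            "wet + light" = "#e08214")) +
    ggplot2::labs(x = NULL, y = "hours per day", colour = NULL) +
    ggplot2::ylim(0, 24) +
    ggplot2::theme_minimal()
}

#' Boxplots of taxon-group relative abundance by site
#'
#' @param table Long abundance tibble with `site`.
#' @param taxonomy Tibble mapping `feature` to the grouping column.
#' @param level Taxonomy column to aggregate by (e.g. `"phylum"`).
#'
#' @return A ggplot object.
#' @export
plot_abundance_boxes <- function(table, taxonomy, level = "phylum") {
  table |>
    left_join(select(taxonomy, "feature", all_of(level)), by = "feature") |>
    group_by(.data$sample, .data$site, .data[[level]]) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$site, .data$abundance,
                                 fill = .data$site)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(level, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative abundance (%)") +
    ggplot2::theme_minimal()
}

#' Ordination scatter for a PCoA result
#'
#' @param object A `halohab_pcoa` object.
#' @param groups Optional group (site) label per sample, used for colour.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot halohab_pcoa
#' @export
autoplot.halohab_pcoa <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (ncol(pts) < 3) pts$Axis2 <- 0
  if (!is.null(groups)) pts$group <- groups
  ve <- function(i) {
    if (length(object$var_explained) >= i) {
      sprintf(" (%.1f%%)", 100 * object$var_explained[i])
    } else ""
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = paste0("PCo1", ve(1)), y = paste0("PCo2", ve(2))) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
      ggplot2::labs(colour = NULL)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Presence/absence grid of osmoadaptation genes
#'
#' @param profile Output of [osmo_gene_profile()].
#'
#' @return A ggplot object (red = present, grey = absent).
#' @export
plot_osmo_profile <- function(profile) {
  profile |>
    mutate(gene = factor(.data$gene, levels = unique(.data$gene))) |>
    ggplot2::ggplot(ggplot2::aes(.data$gene, .data$mag,
                                 fill = .data$present)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::facet_grid(. ~ strategy, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey80"),
                               labels = c(`TRUE` = "present",
                                          `FALSE` = "absent")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Boxplot of per-protein isoelectric points by community
#'
#' @param pi_table Tibble with columns `group` and `pi`.
#'
#' @return A ggplot object.
#' @export
plot_pi_distribution <- function(pi_table) {
  ggplot2::ggplot(pi_table, ggplot2::aes(.data$group, .data$pi,
                                         fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "predicted isoelectric point (pH)") +
    ggplot2::theme_minimal()
}
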