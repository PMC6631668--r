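#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_ribbon
#'   geom_col geom_errorbar labs theme_minimal facet_grid scale_fill_manual
NULL

#' Plot an Fst-versus-heterozygosity outlier scan
#'
#' Loci as points over the interpolated quantile envelope; flagged outliers
#' highlighted.
#'
#' @param object An `outlier_scan` from [fst_outlier_scan()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot outlier_scan
#' @export
autoplot.outlier_scan <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$He, y = .data$fst)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey85", alpha = 0.7
    ) +
    geom_point(aes(colour = .data$outlier), size = 1.4) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"), name = "outlier"
    ) +
    labs(
      x = "Total expected heterozygosity",
      y = expression(F[ST]),
      title = sprintf(
        "Fst outlier scan (%.0f%% envelope)", 100 * attr(object, "envelope_mass")
      )
    ) +
    theme_minimal()
}

#' Plot an informativeness curve
#'
#' Mean informativeness for assignment against panel size, with +/- 1 SD
#' bars and, optionally, the fitted linear regression.
#'
#' @param object An [informativeness_curve()].
#' @param fit Optional [fit_informativeness_regression()] result to overlay.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot informativeness_curve
#' @export
autoplot.informativeness_curve <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$size, y = .data$mean_In)) +
    geom_errorbar(
      aes(
        ymin = .data$mean_In - .data$sd_In,
        ymax = .data$mean_In + .data$sd_In
      ),
      width = 0, colour = "grey60"
    ) +
    geom_point() +
    labs(
      x = "Number of markers",
      y = expression("Informativeness for assignment " * (I[n])),
      title = "Informativeness against panel size"
    ) +
    theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      slope = fit$a, intercept = fit$b, colour = "steelblue"
    )
  }
  p
}

#' Structure-style ancestry barplot
#'
#' One stacked bar per individual showing the captive-bred versus wild
#' ancestry proportions, individuals ordered by `q`.
#'
#' @param object An `admixture_result` from [supervised_admixture()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot admixture_result
#' @export
autoplot.admixture_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(!is.na(.data$q_captive)) %>%
    arrange(.data$q_captive) %>%
    mutate(individual_id = factor(.data$individual_id, levels = .data$individual_id))
  long <- bind_rows(
    df %>% mutate(cluster = "captive-bred", prop = .data$q_captive),
    df %>% mutate(cluster = "wild", prop = 1 - .data$q_captive)
  )
  ggplot(long, aes(x = .data$individual_id, y = .data$prop, fill = .data$cluster)) +
    geom_col(width = 1) +
    scale_fill_manual(values = c("captive-bred" = "grey10", "wild" = "grey75")) +
    labs(x = NULL, y = "Ancestry proportion", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Plot panel marker positions along the linkage map
#'
#' Marker positions per linkage group, the usual visual check that a
#' selected panel covers the map evenly.
#'
#' @param object A [panel_selection()] with mapped positions.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot panel_selection
#' @export
autoplot.panel_selection <- function(object, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$position_cM))
  ggplot(df, aes(
    x = .data$position_cM,
    y = factor(.data$linkage_group, levels = rev(sort(unique(.data$linkage_group))))
  )) +
    geom_point(shape = "|", size = 3) +
    labs(x = "Position (cM)", y = "Linkage group", title = "Panel map coverage") +
    theme_minimal()
}
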