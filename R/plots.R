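#' Plot per-subject rates in the yrTA-yrVE plane
#'
#' Each subject is a point; the quadrants induced by the two cutoffs
#' (when given) correspond to the four rows of the qualitative
#' interpretation table, so the plot reads as a risk map: points right
#' of the yrTA cutoff and below the yrVE cutoff show disproportionate
#' deep-gray atrophy (high risk).
#'
#' @param object A `yrrta_rates` tibble from [compute_rates()].
#' @param ta_cutoff,ve_cutoff Optional cutoffs drawn as dashed lines;
#'   when both are given, points are colored by risk.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yrrta_rates <- function(object, ta_cutoff = NULL, ve_cutoff = NULL,
                                 ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$yrTA, y = .data$yrVE))
  if (!is.null(ta_cutoff) && !is.null(ve_cutoff)) {
    cls <- classify_rates(object, ta_cutoff, ve_cutoff)
    p <- ggplot2::ggplot(cls, ggplot2::aes(x = .data$yrTA, y = .data$yrVE,
                                           color = .data$risk)) +
      ggplot2::geom_vline(xintercept = ta_cutoff, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = ve_cutoff, linetype = "dashed")
  }
  grouped <- "group" %in% names(object) && is.null(ta_cutoff)
  p <- p +
    (if (grouped) ggplot2::geom_point(ggplot2::aes(shape = .data$group))
     else ggplot2::geom_point()) +
    ggplot2::labs(
      x = sprintf("yrTA (%s)",
                  if (identical(attr(object, "mode"), "2d"))
                    "mm²/yr-equivalent" else "mm³/yr-equivalent"),
      y = "yrVE",
      title = "Thalamic atrophy vs ventricular enlargement") +
    ggplot2::theme_minimal()
  p
}

#' Plot group mean yrRTA with SD error bars
#'
#' Bar chart of per-group mean yrRTA, the figure a small
#' proof-of-concept cohort is typically summarized with.
#'
#' @param object A `yrrta_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yrrta_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$yrRTA_mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$yrRTA_mean - .data$yrRTA_sd,
                   ymax = .data$yrRTA_mean + .data$yrRTA_sd),
      width = 0.15) +
    ggplot2::labs(x = NULL, y = "mean yrRTA",
                  title = "Group mean yrRTA",
                  subtitle = sprintf("%s method, %s convention",
                                     toupper(attr(object, "mode") %||% ""),
                                     attr(object, "convention") %||% "")) +
    ggplot2::theme_minimal()
}
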