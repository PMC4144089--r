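#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulated cohort into its measurement table
#'
#' @param x A `yrrta_cohort` from [generate_cohort()].
#' @param mode `"3d"` (default) or `"2d"` — which measurement table to
#'   return.
#' @param ... Unused.
#' @return The per-subject measurement tibble for the mode.
#' @export
tidy.yrrta_cohort <- function(x, mode = c("3d", "2d"), ...) {
  mode <- arg_match(mode)
  if (mode == "3d") x$measurements_3d else x$measurements_2d
}

#' One-row overview of a simulated cohort
#'
#' @param x A `yrrta_cohort`.
#' @param ... Unused.
#' @return One-row tibble: subject counts, grid shape, spacing, seed.
#' @export
glance.yrrta_cohort <- function(x, ...) {
  tibble(n_subjects = sum(x$spec$n),
         n_controls = x$spec$n[["controls"]],
         n_cis_nonprogressor = x$spec$n[["cis_nonprogressor"]],
         n_cis_progressor = x$spec$n[["cis_progressor"]],
         grid = paste(x$spec$base_spec$grid_shape, collapse = "x"),
         spacing_mm = paste(signif(x$spec$base_spec$spacing, 3),
                            collapse = "x"),
         seed = x$spec$seed)
}

#' One-row overview of a rates table
#'
#' @param x A `yrrta_rates` tibble from [compute_rates()].
#' @param ... Unused.
#' @return One-row tibble: subject count, count of undefined yrRTA,
#'   mode, ratio convention and annualization factor used.
#' @export
glance.yrrta_rates <- function(x, ...) {
  tibble(n = nrow(x),
         n_yrRTA_undefined = sum(!x$yrRTA_defined),
         mode = attr(x, "mode") %||% NA_character_,
         convention = attr(x, "convention") %||% NA_character_,
         factor = attr(x, "factor") %||% NA_real_)
}
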