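#' Specification of a simulated longitudinal cohort
#'
#' Mirrors the design of a small proof-of-concept study: three groups —
#' healthy controls, clinically-isolated-syndrome patients who did not
#' progress (CIS-) and CIS patients who progressed to definite MS
#' (CIS+) — each scanned twice 9–15 months apart. Default group sizes
#' are 5/5/5. Per-subject *yearly* thalamic volume-loss and ventricular
#' volume-gain fractions are drawn from group-specific normal
#' distributions (truncated at 0, since a negative loss/gain is
#' meaningless under this scenario) and scaled by the subject's actual
#' inter-scan interval before being applied to the phantom.
#'
#' Default rate parameters: controls and CIS- lose 0.5%/yr of thalamic
#' volume (SD 0.3%) with 1%/yr ventricular gain (SD 0.5%); CIS+ lose
#' 3%/yr (SD 1%) with 2%/yr gain (SD 0.8%). These magnitudes sit in the
#' range reported for healthy aging versus early MS, with the
#' progressor group showing the disproportionate deep-gray atrophy the
#' yrRTA is designed to flag. Mild anatomical between-subject variation
#' is modeled by a global size factor (SD `anatomy_cv`) applied to the
#' base phantom geometry.
#'
#' @param n Integer vector of 3 group sizes, in the order controls,
#'   CIS-, CIS+ (names are fixed).
#' @param loss_mean,loss_sd Yearly thalamic volume-loss fraction mean/SD
#'   per group (length 3, same order).
#' @param gain_mean,gain_sd Yearly ventricular volume-gain fraction
#'   mean/SD per group.
#' @param months_range Inter-scan interval, drawn uniformly (months).
#' @param base_spec The [phantom_spec()] every subject's anatomy is a
#'   scaled copy of.
#' @param anatomy_cv SD of the per-subject global size factor (0 turns
#'   anatomical variation off).
#' @param seed Integer seed; all draws derive from it.
#' @return A `cohort_spec` object (list).
#' @export
cohort_spec <- function(n = c(controls = 5L, cis_nonprogressor = 5L,
                              cis_progressor = 5L),
                        loss_mean = c(0.005, 0.005, 0.03),
                        loss_sd = c(0.003, 0.003, 0.01),
                        gain_mean = c(0.01, 0.01, 0.02),
                        gain_sd = c(0.005, 0.005, 0.008),
                        months_range = c(9, 15),
                        base_spec = phantom_spec(),
                        anatomy_cv = 0.03,
                        seed = 1L) {
  stopifnot(length(n) == 3L, all(n >= 0L),
            length(loss_mean) == 3L, length(loss_sd) == 3L,
            length(gain_mean) == 3L, length(gain_sd) == 3L,
            all(loss_sd >= 0), all(gain_sd >= 0),
            length(months_range) == 2L, all(months_range > 0),
            months_range[1] <= months_range[2],
            anatomy_cv >= 0, inherits(base_spec, "phantom_spec"))
  groups <- c("controls", "cis_nonprogressor", "cis_progressor")
  structure(list(n = setNames(as.integer(n), groups),
                 loss_mean = setNames(loss_mean, groups),
                 loss_sd = setNames(loss_sd, groups),
                 gain_mean = setNames(gain_mean, groups),
                 gain_sd = setNames(gain_sd, groups),
                 months_range = months_range,
                 base_spec = base_spec,
                 anatomy_cv = anatomy_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

scale_phantom_spec <- function(spec, k) {
  spec$thalamus_semi_axes <- spec$thalamus_semi_axes * k
  spec$thalamus_offset_x <- spec$thalamus_offset_x * k
  spec$tv_width <- spec$tv_width * k
  spec$tv_half_length <- spec$tv_half_length * k
  spec$tv_z_range <- spec$tv_z_range * k
  spec$tv_peak_z <- spec$tv_peak_z * k
  spec$lv_radius <- spec$lv_radius * k
  spec$lv_thickness <- spec$lv_thickness * k
  spec$lv_half_length <- spec$lv_half_length * k
  spec
}

#' Simulate a cohort through the full measurement pipeline
#'
#' For every subject: draws a size factor, a per-year thalamic-loss and
#' ventricular-gain fraction from the subject's group distribution
#' (truncated at 0) and an inter-scan interval; generates the baseline
#' phantom; applies the interval-scaled change with [apply_change()];
#' and measures *both* timepoints with the morphometry module, in 2D
#' (reference-slice areas) and 3D (volumes). All randomness flows from
#' the single seed in the spec, so equal specs give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A `yrrta_cohort`: list with `measurements_2d` and
#'   `measurements_3d` (measurement tibbles with `subject_id`, `group`
#'   and `months`), `truth` (per-subject applied fractions and
#'   ground-truth volumes), and `spec`.
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_spec(n = c(2, 2, 2), seed = 7))
#' co$measurements_3d
#' }
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rows2d <- list(); rows3d <- list(); truths <- list()
  k <- 0L
  for (grp in names(spec$n)) {
    for (i in seq_len(spec$n[[grp]])) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", grp, i)
      size <- max(0.8, rnorm(1, 1, spec$anatomy_cv))
      loss_yr <- max(0, rnorm(1, spec$loss_mean[[grp]], spec$loss_sd[[grp]]))
      gain_yr <- max(0, rnorm(1, spec$gain_mean[[grp]], spec$gain_sd[[grp]]))
      months <- runif(1, spec$months_range[1], spec$months_range[2])
      pspec <- scale_phantom_spec(spec$base_spec, size)
      base <- generate_phantom(pspec)
      fu <- apply_change(base, min(loss_yr * months / 12, 0.99),
                         gain_yr * months / 12)
      m2_1 <- extract_measurements_2d(base$volume, check_midline = FALSE)
      # phantom anatomy does not move between scans, so the follow-up is
      # measured on the baseline's reference slice (slice re-selection
      # noise is a property of landmark re-identification, not simulated)
      m2_2 <- extract_measurements_2d(fu$volume, check_midline = FALSE,
                                      slice_override = m2_1$slice_index)
      m3_1 <- suppressWarnings(
        extract_measurements_3d(base$volume, check_midline = FALSE))
      m3_2 <- suppressWarnings(
        extract_measurements_3d(fu$volume, check_midline = FALSE))
      r2 <- pair_measurements(m2_1, m2_2, months, sid)
      r3 <- pair_measurements(m3_1, m3_2, months, sid)
      r2$group <- grp; r3$group <- grp
      rows2d[[k]] <- r2; rows3d[[k]] <- r3
      tr <- fu$truth
      tr$subject_id <- sid; tr$group <- grp
      tr$months <- months
      tr$baseline_voxel_count <- base$truth$voxel_count
      tr$baseline_volume_mm3 <- base$truth$volume_mm3
      truths[[k]] <- tr
    }
  }
  empty_cols <- function(mode) {
    cols <- c("subject_id", required_measure_cols(mode), "group")
    tbl <- as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
    tbl$subject_id <- character(0); tbl$group <- character(0)
    tbl
  }
  structure(list(
    measurements_2d = if (k == 0L) empty_cols("2d") else bind_rows(rows2d),
    measurements_3d = if (k == 0L) empty_cols("3d") else bind_rows(rows3d),
    truth = bind_rows(truths),
    spec = spec),
    class = "yrrta_cohort")
}

#' @export
print.yrrta_cohort <- function(x, ...) {
  cat(sprintf("<yrrta_cohort> %d subjects (%s), seed %d\n",
              sum(x$spec$n),
              paste(sprintf("%s=%d", names(x$spec$n), x$spec$n),
                    collapse = ", "),
              x$spec$seed))
  invisible(x)
}

#' Per-group summary of computed rates
#'
#' Group-level reporting in the style of a proof-of-concept table:
#' per-group subject count, mean and SD of yrTA, yrVE and yrRTA. The
#' yrRTA statistics use defined values only; subjects whose yrRTA is
#' undefined (zero ventricular change) are counted in
#' `n_yrRTA_undefined`, never imputed. A single-subject group reports
#' SD 0.
#'
#' @param rates A rates table from [compute_rates()] with a grouping
#'   column.
#' @param group Name of the grouping column (default `"group"`).
#' @return A `yrrta_summary` tibble: one row per group with `n`,
#'   `yrTA_mean`, `yrTA_sd`, `yrVE_mean`, `yrVE_sd`, `yrRTA_mean`,
#'   `yrRTA_sd`, `n_yrRTA_defined`, `n_yrRTA_undefined`.
#' @export
summarize_cohort <- function(rates, group = "group") {
  if (!group %in% names(rates)) {
    abort(paste0("Grouping column `", group, "` not found."),
          class = "yrrta_validation_error")
  }
  for (col in c("yrTA", "yrVE", "yrRTA")) {
    if (!col %in% names(rates)) {
      abort(paste0("Missing column `", col,
                   "`; run compute_rates() first."),
            class = "yrrta_schema_error")
    }
  }
  sd0 <- function(x) if (length(x) <= 1L) 0 else sd(x)
  out <- as_tibble(rates) |>
    group_by(.data[[group]]) |>
    summarise(
      n = n(),
      yrTA_mean = mean(.data$yrTA),
      yrTA_sd = sd0(.data$yrTA),
      yrVE_mean = mean(.data$yrVE),
      yrVE_sd = sd0(.data$yrVE),
      yrRTA_mean = mean(.data$yrRTA[!is.na(.data$yrRTA)]),
      yrRTA_sd = sd0(.data$yrRTA[!is.na(.data$yrRTA)]),
      n_yrRTA_defined = sum(!is.na(.data$yrRTA)),
      n_yrRTA_undefined = sum(is.na(.data$yrRTA)),
      .groups = "drop")
  names(out)[1] <- "group"
  attr(out, "mode") <- attr(rates, "mode")
  attr(out, "convention") <- attr(rates, "convention")
  class(out) <- c("yrrta_summary", class(out))
  out
}
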