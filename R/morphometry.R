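#' Per-slice voxel counts for a set of labels
#' @noRd
slice_counts <- function(vol, label_ids) {
  d <- dim(vol$voxels)
  m <- matrix(vol$voxels %in% as.integer(label_ids), nrow = d[1] * d[2])
  colSums(m)
}

#' Select the reference axial slice
#'
#' Operationalizes the anatomical instruction "the axial slice passing
#' through the foramen of Monro / interthalamic adhesion": among the
#' axial slices on which *both* thalami are present, returns the slice
#' with the largest third-ventricle cross-sectional area. The
#' interthalamic adhesion crosses the third ventricle at the level where
#' the two thalami flank it, so this maximizer is the in-mask analogue
#' of the landmark a human tracer would pick. Ties are broken toward the
#' most inferior (lowest-index) slice, making the selection
#' deterministic. Slice indices are 1-based.
#'
#' @param vol A [label_volume()].
#' @param labels A [label_map()].
#' @return A one-row tibble: `slice_index`, `third_ventricle_area_mm2`,
#'   `both_thalami_present` (always `TRUE` for a returned selection).
#' @export
select_reference_slice <- function(vol, labels = label_map()) {
  stopifnot(inherits(vol, "label_volume"))
  cnt_r <- slice_counts(vol, labels[["thalamus_right"]])
  cnt_l <- slice_counts(vol, labels[["thalamus_left"]])
  candidates <- cnt_r > 0L & cnt_l > 0L
  if (!any(candidates)) {
    missing_side <- if (!any(cnt_r > 0L)) "right thalamus"
                    else if (!any(cnt_l > 0L)) "left thalamus"
                    else "both thalami on a common slice"
    abort(paste0("No axial slice contains both thalami (missing: ",
                 missing_side, ")."),
          class = "yrrta_selection_error")
  }
  cnt_d <- slice_counts(vol, labels[["third_ventricle"]])
  score <- ifelse(candidates, cnt_d, -Inf)
  idx <- which.max(score)  # which.max returns the first (most inferior) tie
  tibble(slice_index = as.integer(idx),
         third_ventricle_area_mm2 = cnt_d[idx] * prod(vol$spacing[1:2]),
         both_thalami_present = TRUE)
}

#' Cross-sectional area of labels on one axial slice
#'
#' Planimetric area: the number of voxels on the slice whose label is in
#' `label_ids`, times the in-plane pixel area (spacing_x * spacing_y).
#' Labels are binary per voxel — no partial-volume weighting — matching
#' manual tracing in a DICOM viewer.
#'
#' @param vol A [label_volume()].
#' @param label_ids Integer vector of label values (a union of labels is
#'   measured as one region).
#' @param slice_index 1-based axial slice index.
#' @return Area in mm^2.
#' @export
region_area <- function(vol, label_ids, slice_index) {
  stopifnot(inherits(vol, "label_volume"))
  if (length(slice_index) != 1L || slice_index < 1L ||
      slice_index > n_slices(vol)) {
    abort(sprintf("slice_index %s out of range [1, %d].",
                  format(slice_index), n_slices(vol)),
          class = "yrrta_bounds_error")
  }
  sl <- vol$voxels[, , slice_index]
  sum(sl %in% as.integer(label_ids)) * prod(vol$spacing[1:2])
}

#' Volume of labels in a label volume
#'
#' Voxel-counting volumetry: the number of voxels whose label is in
#' `label_ids`, times the voxel volume (product of the three spacings).
#'
#' @inheritParams region_area
#' @return Volume in mm^3.
#' @export
region_volume <- function(vol, label_ids) {
  stopifnot(inherits(vol, "label_volume"))
  sum(vol$voxels %in% as.integer(label_ids)) * prod(vol$spacing)
}

#' Warn when the two thalamus labels touch across the midline
#'
#' The tracing protocol requires left and right thalamus to be delineated
#' individually, excluding the interthalamic adhesion (massa intermedia).
#' In mask space that exclusion is the segmenter's job; this check flags
#' the detectable violation — a 6-connected face contact between the two
#' thalamus labels.
#' @noRd
check_midline_bridge <- function(vol, labels) {
  v <- vol$voxels
  r <- labels[["thalamus_right"]]; l <- labels[["thalamus_left"]]
  d <- dim(v)
  touch <-
    any(v[-d[1], , ] == r & v[-1, , ] == l) ||
    any(v[-d[1], , ] == l & v[-1, , ] == r) ||
    any(v[, -d[2], ] == r & v[, -1, ] == l) ||
    any(v[, -d[2], ] == l & v[, -1, ] == r) ||
    any(v[, , -d[3]] == r & v[, , -1] == l) ||
    any(v[, , -d[3]] == l & v[, , -1] == r)
  if (touch) {
    warn(paste("Left and right thalamus labels are 6-connected:",
               "the segmentation may include the interthalamic adhesion,",
               "which the tracing protocol excludes."),
         class = "yrrta_midline_warning")
  }
  invisible(touch)
}

#' Planimetric (2D) measurements on the reference slice
#'
#' Measures, on a single axial slice, the areas the 2D method needs:
#' `area_A` and `area_A_prime` (right and left thalamus) and `area_B`
#' (the whole ventricular system — the union of both lateral-ventricle
#' labels and the third-ventricle label; any posterior/occipital horns
#' carried by the lateral-ventricle labels are included by that union).
#' The slice is chosen by [select_reference_slice()] unless overridden.
#'
#' @param vol A [label_volume()].
#' @param labels A [label_map()].
#' @param slice_override Optional 1-based slice index, for protocol
#'   fidelity when a human has already picked the landmark slice.
#' @param check_midline If `TRUE` (default), warn when the two thalamus
#'   labels are face-adjacent (possible interthalamic-adhesion bridging).
#' @return One-row tibble: `slice_index`, `area_A`, `area_A_prime`,
#'   `area_B` (mm^2).
#' @export
extract_measurements_2d <- function(vol, labels = label_map(),
                                    slice_override = NULL,
                                    check_midline = TRUE) {
  stopifnot(inherits(vol, "label_volume"))
  if (check_midline) check_midline_bridge(vol, labels)
  slice <- if (is.null(slice_override)) {
    select_reference_slice(vol, labels)$slice_index
  } else {
    if (slice_override < 1L || slice_override > n_slices(vol)) {
      abort(sprintf("slice_override %s out of range [1, %d].",
                    format(slice_override), n_slices(vol)),
            class = "yrrta_bounds_error")
    }
    as.integer(slice_override)
  }
  tibble(
    slice_index = slice,
    area_A = region_area(vol, labels[["thalamus_right"]], slice),
    area_A_prime = region_area(vol, labels[["thalamus_left"]], slice),
    area_B = region_area(vol, labels[ventricle_roles], slice))
}

#' Volumetric (3D) measurements
#'
#' Measures the five volumes the 3D method needs: right/left thalamus
#' (`vol_A`, `vol_A_prime`), right/left lateral ventricle (`vol_C`,
#' `vol_C_prime`) and third ventricle (`vol_D`). A structure absent from
#' the volume yields 0 mm^3 with a warning.
#'
#' @inheritParams extract_measurements_2d
#' @return One-row tibble with the five volumes in mm^3.
#' @export
extract_measurements_3d <- function(vol, labels = label_map(),
                                    check_midline = TRUE) {
  stopifnot(inherits(vol, "label_volume"))
  if (check_midline) check_midline_bridge(vol, labels)
  vols <- vapply(names(labels), function(role) {
    region_volume(vol, labels[[role]])
  }, numeric(1))
  absent <- names(vols)[vols == 0]
  if (length(absent) > 0L) {
    warn(paste0("Structure(s) absent from volume (0 mm^3): ",
                paste(absent, collapse = ", ")),
         class = "yrrta_absent_structure_warning")
  }
  tibble(
    vol_A = vols[["thalamus_right"]],
    vol_A_prime = vols[["thalamus_left"]],
    vol_C = vols[["lateral_ventricle_right"]],
    vol_C_prime = vols[["lateral_ventricle_left"]],
    vol_D = vols[["third_ventricle"]])
}

#' Build a one-row paired-timepoint measurement table
#'
#' Combines baseline and follow-up timepoint measurements (both 2D, from
#' [extract_measurements_2d()], or both 3D, from
#' [extract_measurements_3d()]) with the inter-scan interval into the
#' column dialect [compute_rates()] and [read_measurement_table()] use:
#' `A1, A_prime1, B1, A2, A_prime2, B2, months` (2D) or
#' `A1, A_prime1, C1, C_prime1, D1, A2, ..., months` (3D).
#'
#' @param baseline,followup One-row tibbles from the same extractor.
#' @param months Positive inter-scan interval in months (see
#'   [months_between()] to derive it from two dates).
#' @param subject_id Subject identifier string.
#' @return One-row measurement tibble.
#' @export
pair_measurements <- function(baseline, followup, months,
                              subject_id = "subject") {
  if (!is.numeric(months) || length(months) != 1L || !is.finite(months) ||
      months <= 0) {
    abort("`months` must be a single positive number.",
          class = "yrrta_validation_error")
  }
  is2d <- "area_A" %in% names(baseline)
  if (is2d != ("area_A" %in% names(followup))) {
    abort("baseline and follow-up must have the same dimensionality (2D/3D).",
          class = "yrrta_validation_error")
  }
  if (is2d) {
    tibble(subject_id = subject_id,
           A1 = baseline$area_A, A_prime1 = baseline$area_A_prime,
           B1 = baseline$area_B,
           A2 = followup$area_A, A_prime2 = followup$area_A_prime,
           B2 = followup$area_B,
           months = months)
  } else {
    tibble(subject_id = subject_id,
           A1 = baseline$vol_A, A_prime1 = baseline$vol_A_prime,
           C1 = baseline$vol_C, C_prime1 = baseline$vol_C_prime,
           D1 = baseline$vol_D,
           A2 = followup$vol_A, A_prime2 = followup$vol_A_prime,
           C2 = followup$vol_C, C_prime2 = followup$vol_C_prime,
           D2 = followup$vol_D,
           months = months)
  }
}

#' Inter-scan interval in months from two dates
#'
#' The method counts the interval in months without defining a month;
#' this helper fixes the convention as days / 30.4375 (the mean Gregorian
#' month). An explicitly supplied month count always takes precedence in
#' the CLI.
#'
#' @param start,end Dates or ISO `"YYYY-MM-DD"` strings; `end` must be
#'   after `start`.
#' @return Interval in months (positive real).
#' @examples
#' months_between("2020-01-01", "2021-01-01")
#' @export
months_between <- function(start, end) {
  d <- as.numeric(difftime(as.Date(end), as.Date(start), units = "days"))
  if (!is.finite(d) || d <= 0) {
    abort("`end` must be after `start`.", class = "yrrta_validation_error")
  }
  d / 30.4375
}
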