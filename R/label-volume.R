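#' Construct a segmentation label volume
#'
#' A `label_volume` is the substrate of every measurement in the package:
#' a 3D grid of non-negative integer structure labels (0 = background /
#' unsegmented tissue) together with the physical voxel spacing in mm.
#' The third array axis is, by convention, the axial (inferior-to-superior)
#' axis, so `voxels[, , k]` is the k-th axial slice counted from the most
#' inferior slice; slice indices are 1-based throughout the package.
#'
#' @param voxels 3D array of non-negative integer labels (at least one
#'   voxel along every axis). Numeric arrays holding whole numbers are
#'   accepted and stored as integer.
#' @param spacing Numeric vector of 3 positive voxel sizes in mm
#'   (in-plane x, in-plane y, slice/axial z).
#' @return An object of class `label_volume`: a list with elements
#'   `voxels` (integer array) and `spacing` (double of length 3).
#' @examples
#' vox <- array(0L, c(4, 4, 3))
#' vox[2:3, 2:3, 2] <- 1L
#' vol <- label_volume(vox, spacing = c(1, 1, 3))
#' region_volume(vol, 1)
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array.", class = "yrrta_data_error")
  }
  if (any(dim(voxels) < 1L)) {
    abort("`voxels` must have at least one voxel along every axis.",
          class = "yrrta_data_error")
  }
  if (!is.numeric(spacing) || length(spacing) != 3L ||
      any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 finite positive voxel sizes in mm.",
          class = "yrrta_header_error")
  }
  v <- voxels
  if (!is.integer(v)) {
    if (any(!is.finite(v)) || any(v != round(v))) {
      abort("`voxels` must contain only finite whole-number label values.",
            class = "yrrta_data_error")
    }
    storage.mode(v) <- "integer"
  }
  if (any(v < 0L)) {
    abort("Label values must be >= 0 (0 = background).",
          class = "yrrta_data_error")
  }
  structure(list(voxels = v, spacing = as.double(spacing)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- sort(unique(as.vector(x$voxels)))
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  labels:", paste(head(labs, 12L), collapse = " "),
      if (length(labs) > 12L) "..." else "", "\n")
  invisible(x)
}

n_slices <- function(vol) dim(vol$voxels)[3]

#' Map anatomical roles to label identifiers
#'
#' Associates the five structures needed by the method — right/left
#' thalamus (symbols A / A'), right/left lateral ventricle (C / C') and
#' third ventricle (D) — with integer label values in a segmentation.
#' Two presets are built in: `"default"` (labels 1–5, matching the
#' phantom generator) and `"aseg"` (the FreeSurfer aseg convention:
#' 49, 10, 43, 4, 14). Individual roles can be overridden.
#'
#' @param preset `"default"` or `"aseg"`.
#' @param thalamus_right,thalamus_left,lateral_ventricle_right,lateral_ventricle_left,third_ventricle
#'   Optional single integer overrides for individual roles.
#' @return Named integer vector of class `label_map` with the five roles.
#' @examples
#' label_map()
#' label_map("aseg")
#' label_map(third_ventricle = 99)
#' @export
label_map <- function(preset = c("default", "aseg"),
                      thalamus_right = NULL, thalamus_left = NULL,
                      lateral_ventricle_right = NULL,
                      lateral_ventricle_left = NULL,
                      third_ventricle = NULL) {
  preset <- arg_match(preset)
  base <- switch(preset,
    default = c(thalamus_right = 1L, thalamus_left = 2L,
                lateral_ventricle_right = 3L, lateral_ventricle_left = 4L,
                third_ventricle = 5L),
    aseg = c(thalamus_right = 49L, thalamus_left = 10L,
             lateral_ventricle_right = 43L, lateral_ventricle_left = 4L,
             third_ventricle = 14L))
  over <- list(thalamus_right = thalamus_right, thalamus_left = thalamus_left,
               lateral_ventricle_right = lateral_ventricle_right,
               lateral_ventricle_left = lateral_ventricle_left,
               third_ventricle = third_ventricle)
  for (role in names(over)) {
    if (!is.null(over[[role]])) base[[role]] <- as.integer(over[[role]])
  }
  if (any(base <= 0L) || anyDuplicated(base) > 0L) {
    abort("The five roles must map to five distinct nonzero labels.",
          class = "yrrta_data_error")
  }
  structure(base, class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map>\n")
  for (role in names(x)) cat(sprintf("  %-24s %d\n", role, x[[role]]))
  invisible(x)
}

ventricle_roles <- c("lateral_ventricle_right", "lateral_ventricle_left",
                     "third_ventricle")
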