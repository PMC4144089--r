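#' Specification of a synthetic brain phantom
#'
#' Describes the geometry of a five-structure deep-brain phantom used to
#' verify the measurement pipeline end to end: two ellipsoidal thalami
#' flanking a midline third-ventricle slab, and two arc-shaped (partial
#' cylindrical shell) lateral ventricles superior-lateral to the
#' thalami. All dimensions are in mm in a coordinate frame centered on
#' the grid; the third axis is axial (inferior-to-superior). The
#' geometry is a test fixture, not an anatomical atlas: sizes are chosen
#' to be of realistic magnitude (thalami ~3.4 cm^3 each, lateral
#' ventricles ~2.4 cm^3 each, third ventricle ~0.7 cm^3) with clear
#' margins so the rasterized structures stay pairwise disjoint.
#'
#' The third-ventricle slab has a parabolic width profile along the
#' axial axis (widest at `tv_peak_z`), giving a unique
#' maximal-cross-section slice for the reference-slice rule.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param spacing Voxel size in mm (scalar, expanded, or length 3).
#' @param thalamus_semi_axes Semi-axes (x, y, z) in mm of each thalamus
#'   ellipsoid.
#' @param thalamus_offset_x Distance of each thalamus center from the
#'   midline, mm.
#' @param tv_width,tv_half_length,tv_z_range,tv_peak_z Third-ventricle
#'   slab: maximal width (x extent, mm), half-length along y (mm), axial
#'   extent `c(lo, hi)` (mm), and the z of maximal width.
#' @param lv_radius,lv_thickness,lv_theta_range,lv_half_length Lateral
#'   ventricle arcs: shell radius and thickness (mm), angular extent in
#'   degrees in the x-z plane measured from the lateral direction
#'   (90 = straight up), and half-length along y (mm).
#' @param seed Integer seed recorded with the spec (generation itself is
#'   deterministic; the seed is consumed by cohort-level sampling).
#' @return A `phantom_spec` object (list).
#' @seealso [generate_phantom()], [apply_change()]
#' @export
phantom_spec <- function(grid_shape = c(32L, 28L, 22L),
                         spacing = c(2, 2, 2),
                         thalamus_semi_axes = c(9, 13, 7),
                         thalamus_offset_x = 12,
                         tv_width = 3, tv_half_length = 12,
                         tv_z_range = c(-6, 4), tv_peak_z = 0,
                         lv_radius = 12, lv_thickness = 3,
                         lv_theta_range = c(-15, 155),
                         lv_half_length = 16,
                         seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(thalamus_semi_axes) == 3L, all(thalamus_semi_axes > 0),
            tv_width > 0, tv_half_length > 0, length(tv_z_range) == 2L,
            tv_z_range[1] < tv_z_range[2],
            lv_radius > 0, lv_thickness > 0, lv_half_length > 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.double(spacing),
                 thalamus_semi_axes = thalamus_semi_axes,
                 thalamus_offset_x = thalamus_offset_x,
                 tv_width = tv_width, tv_half_length = tv_half_length,
                 tv_z_range = tv_z_range, tv_peak_z = tv_peak_z,
                 lv_radius = lv_radius, lv_thickness = lv_thickness,
                 lv_theta_range = lv_theta_range,
                 lv_half_length = lv_half_length,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Voxel-center coordinate vectors (mm, grid-centered)
#' @noRd
grid_coords <- function(spec) {
  lapply(1:3, function(ax) {
    n <- spec$grid_shape[ax]; h <- spec$spacing[ax]
    (seq_len(n) - (n + 1) / 2) * h
  })
}

#' Rasterize an ellipsoid: voxel centers inside count as in
#' @noRd
rasterize_ellipsoid <- function(coords, center, semi) {
  dx2 <- ((coords[[1]] - center[1]) / semi[1])^2
  dy2 <- ((coords[[2]] - center[2]) / semi[2])^2
  dz2 <- ((coords[[3]] - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Rasterize the third-ventricle slab (parabolic width profile in z)
#' @noRd
rasterize_slab <- function(coords, spec) {
  z <- coords[[3]]
  zr <- spec$tv_z_range
  span <- max(spec$tv_peak_z - zr[1], zr[2] - spec$tv_peak_z)
  wz <- ifelse(z >= zr[1] & z <= zr[2],
               spec$tv_width * (1 - ((z - spec$tv_peak_z) / span)^2),
               -1)
  inx <- outer(abs(coords[[1]]), wz / 2, "<=") # nx x nz
  iny <- abs(coords[[2]]) <= spec$tv_half_length
  ok_w <- matrix(wz > 0, nrow = length(coords[[1]]),
                 ncol = length(z), byrow = TRUE)
  aperm(outer(inx & ok_w, iny, "&"), c(1, 3, 2))
}

#' Rasterize one lateral-ventricle arc (partial cylindrical shell,
#' axis parallel to y through (x0, z = 0))
#' @noRd
rasterize_arc <- function(coords, spec, side) {
  x0 <- side * spec$thalamus_offset_x
  dx <- coords[[1]] - x0
  dz <- coords[[3]]
  r <- sqrt(outer(dx^2, dz^2, "+"))
  # angle from the lateral (outward) direction, in the upper half-plane
  theta <- atan2(outer(rep(1, length(dx)), dz),
                 side * outer(dx, rep(1, length(dz)))) * 180 / pi
  shell <- r >= spec$lv_radius - spec$lv_thickness / 2 &
           r <= spec$lv_radius + spec$lv_thickness / 2 &
           theta >= spec$lv_theta_range[1] & theta <= spec$lv_theta_range[2]
  iny <- abs(coords[[2]]) <= spec$lv_half_length
  aperm(outer(shell, iny, "&"), c(1, 3, 2))
}

phantom_roles <- c("thalamus_right", "thalamus_left",
                   "lateral_ventricle_right", "lateral_ventricle_left",
                   "third_ventricle")

#' Generate a synthetic phantom with exact ground truth
#'
#' Rasterizes the five structures of a [phantom_spec()] into a
#' [label_volume()] (default label map: thalamus right/left = 1/2,
#' lateral ventricle right/left = 3/4, third ventricle = 5) and records
#' the exact per-structure voxel counts and volumes as ground truth.
#' Generation is fully deterministic. Overlapping structures (e.g.
#' thalami centered on the midline) abort with the colliding pair named.
#'
#' @param spec A [phantom_spec()].
#' @return A `yrrta_phantom`: list with `volume` ([label_volume()]),
#'   `truth` (tibble: `role`, `label`, `voxel_count`, `volume_mm3`),
#'   and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec())
#' ph$truth
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  coords <- grid_coords(spec)
  masks <- list(
    thalamus_right = rasterize_ellipsoid(
      coords, c(spec$thalamus_offset_x, 0, 0), spec$thalamus_semi_axes),
    thalamus_left = rasterize_ellipsoid(
      coords, c(-spec$thalamus_offset_x, 0, 0), spec$thalamus_semi_axes),
    lateral_ventricle_right = rasterize_arc(coords, spec, +1),
    lateral_ventricle_left = rasterize_arc(coords, spec, -1),
    third_ventricle = rasterize_slab(coords, spec))
  counts <- vapply(masks, sum, numeric(1))
  if (any(counts == 0)) {
    abort(paste0("Structure(s) rasterize to zero voxels (grid too small ",
                 "or too coarse): ",
                 paste(names(counts)[counts == 0], collapse = ", ")),
          class = "yrrta_spec_error")
  }
  # pairwise-disjointness check, naming the first colliding pair
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]])) {
        abort(paste0("Structures overlap after rasterization: ",
                     names(masks)[j], " / ", names(masks)[i]),
              class = "yrrta_spec_error")
      }
    }
  }
  labels <- label_map()
  vox <- array(0L, spec$grid_shape)
  for (role in phantom_roles) vox[masks[[role]]] <- labels[[role]]
  vol <- label_volume(vox, spacing = spec$spacing)
  # both thalami and the third ventricle must share at least one slice
  sel <- select_reference_slice(vol, labels)
  if (sel$third_ventricle_area_mm2 <= 0) {
    abort("No axial slice holds both thalami and the third ventricle.",
          class = "yrrta_spec_error")
  }
  truth <- tibble(role = phantom_roles,
                  label = as.integer(labels[phantom_roles]),
                  voxel_count = as.integer(counts[phantom_roles]),
                  volume_mm3 = unname(counts[phantom_roles]) *
                    prod(spec$spacing))
  structure(list(volume = vol, truth = truth, spec = spec),
            class = "yrrta_phantom")
}

#' @export
print.yrrta_phantom <- function(x, ...) {
  cat("<yrrta_phantom>\n")
  print(x$volume)
  print(x$truth)
  invisible(x)
}

shift6 <- function(m, pad) {
  d <- dim(m)
  out <- list()
  p1 <- array(pad, c(1L, d[2], d[3]))
  p2 <- array(pad, c(d[1], 1L, d[3]))
  p3 <- array(pad, c(d[1], d[2], 1L))
  idx <- function(n) list(lo = seq_len(n - 1L), hi = seq_len(n - 1L) + 1L)
  i1 <- idx(d[1]); i2 <- idx(d[2]); i3 <- idx(d[3])
  list(
    abind3(p1, m[i1$lo, , , drop = FALSE], along = 1L),
    abind3(m[i1$hi, , , drop = FALSE], p1, along = 1L),
    abind3(p2, m[, i2$lo, , drop = FALSE], along = 2L),
    abind3(m[, i2$hi, , drop = FALSE], p2, along = 2L),
    abind3(p3, m[, , i3$lo, drop = FALSE], along = 3L),
    abind3(m[, , i3$hi, drop = FALSE], p3, along = 3L))
}

# minimal 3D array binding (avoids an extra dependency)
abind3 <- function(a, b, along) {
  da <- dim(a); db <- dim(b)
  d <- da; d[along] <- da[along] + db[along]
  out <- array(vector(mode = typeof(a), 1L), d)
  ia <- lapply(seq_len(3L), function(k) seq_len(da[k]))
  ib <- lapply(seq_len(3L), function(k) {
    if (k == along) da[k] + seq_len(db[k]) else seq_len(db[k])
  })
  out[ia[[1]], ia[[2]], ia[[3]]] <- a
  out[ib[[1]], ib[[2]], ib[[3]]] <- b
  out
}

# Deterministic low-discrepancy ordering of voxel indices (golden-ratio
# hash): used to trim a partial erosion/dilation layer so that the
# trimmed voxels are spread over the whole layer instead of clustered at
# one end of the structure, approximating spatially uniform sub-voxel
# boundary displacement.
spread_order <- function(idx) {
  phi <- (sqrt(5) - 1) / 2
  idx[order((idx * phi) %% 1, idx)]
}

erode6 <- function(m) {
  s <- shift6(m, FALSE)
  m & s[[1]] & s[[2]] & s[[3]] & s[[4]] & s[[5]] & s[[6]]
}

dilate6 <- function(m) {
  s <- shift6(m, FALSE)
  m | s[[1]] | s[[2]] | s[[3]] | s[[4]] | s[[5]] | s[[6]]
}

#' Interior depth (6-connected peeling distance): number of erosion
#' passes a voxel survives; boundary layer = 1.
#' @noRd
peel_depth <- function(mask) {
  d <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    d[cur] <- k
    cur <- erode6(cur)
  }
  d
}

#' Shrink a mask to an exact voxel count from the outside in
#'
#' Voxels are ranked by interior depth (descending), ties broken by
#' linear index, and the deepest `target` voxels are kept. This is
#' morphological erosion refined to an exact count: bisection over a
#' depth threshold brackets the target and the tie layer is trimmed
#' deterministically.
#' @noRd
shrink_to_count <- function(mask, target) {
  n0 <- sum(mask)
  if (target >= n0) return(mask)
  if (target < 0L) {
    abort("Target count below zero is unreachable.",
          class = "yrrta_change_error")
  }
  depth <- peel_depth(mask)
  # deepest voxels survive; the partially-removed boundary layer is
  # trimmed in spread order
  out <- array(FALSE, dim(mask))
  n_kept <- 0L
  for (k in sort(unique(depth[mask]), decreasing = TRUE)) {
    layer <- which(depth == k & mask)
    room <- target - n_kept
    if (length(layer) <= room) {
      out[layer] <- TRUE
      n_kept <- n_kept + length(layer)
    } else {
      out[spread_order(layer)[seq_len(room)]] <- TRUE
      n_kept <- target
    }
    if (n_kept >= target) break
  }
  out
}

#' Grow a mask into allowed background to an exact voxel count
#'
#' Adds background voxels layer by layer (6-connected dilation rings),
#' trimming the final ring deterministically by linear index. Growth is
#' restricted to voxels where `allowed` is TRUE (background), so a
#' ventricle never claims another structure's voxels.
#' @noRd
grow_to_count <- function(mask, allowed, target) {
  n0 <- sum(mask)
  if (target <= n0) return(mask)
  need <- target - n0
  out <- mask
  while (need > 0L) {
    ring <- dilate6(out) & !out & allowed
    nring <- sum(ring)
    if (nring == 0L) {
      abort(sprintf(paste("Growth target unreachable: no adjacent",
                          "background left (achievable count: %d of %d)."),
                    sum(out), target),
            class = "yrrta_change_error")
    }
    if (nring <= need) {
      out <- out | ring
      need <- need - nring
    } else {
      take <- spread_order(which(ring))[seq_len(need)]
      out[take] <- TRUE
      need <- 0L
    }
  }
  out
}

#' Apply longitudinal change to a phantom
#'
#' Simulates follow-up anatomy with exact, recountable ground truth:
#' each thalamus is shrunk toward its interior until its voxel count
#' equals `round((1 - thalamus_loss_fraction) * original)`, then each
#' ventricular structure is grown into background until its count equals
#' `round((1 + ventricle_gain_fraction) * original)`. Shrinking uses an
#' interior-distance (peeling) ranking and growth uses dilation rings,
#' both with deterministic tie-breaking, so target counts are hit
#' exactly. Thalami are shrunk first, freeing background the ventricles
#' may then claim (thalamic atrophy feeding third-ventricle enlargement);
#' ventricle and thalamus labels never exchange voxels directly, and
#' structures remain pairwise disjoint.
#'
#' @param phantom A `yrrta_phantom` from [generate_phantom()].
#' @param thalamus_loss_fraction Fractional thalamic volume loss over
#'   the interval, in `[0, 1)`.
#' @param ventricle_gain_fraction Fractional ventricular volume gain
#'   over the interval, `>= 0`.
#' @return A `yrrta_phantom` for the follow-up timepoint; its `truth`
#'   carries the updated counts plus the applied fractions in columns
#'   `applied_loss_fraction` / `applied_gain_fraction`.
#' @examples
#' base <- generate_phantom(phantom_spec())
#' fu <- apply_change(base, 0.03, 0.02)
#' fu$truth
#' @export
apply_change <- function(phantom, thalamus_loss_fraction,
                         ventricle_gain_fraction) {
  stopifnot(inherits(phantom, "yrrta_phantom"))
  f <- thalamus_loss_fraction; g <- ventricle_gain_fraction
  if (!is.finite(f) || f < 0 || f >= 1) {
    abort("`thalamus_loss_fraction` must be in [0, 1).",
          class = "yrrta_validation_error")
  }
  if (!is.finite(g) || g < 0) {
    abort("`ventricle_gain_fraction` must be >= 0.",
          class = "yrrta_validation_error")
  }
  vox <- phantom$volume$voxels
  truth <- phantom$truth
  lab_of <- setNames(truth$label, truth$role)
  cnt_of <- setNames(truth$voxel_count, truth$role)

  for (role in c("thalamus_right", "thalamus_left")) {
    target <- as.integer(round((1 - f) * cnt_of[[role]]))
    if (target < 1L) {
      abort(sprintf("Loss fraction %.3g leaves %s with no voxels.", f, role),
            class = "yrrta_change_error")
    }
    mask <- vox == lab_of[[role]]
    new_mask <- shrink_to_count(mask, target)
    vox[mask & !new_mask] <- 0L  # freed tissue becomes background
  }
  for (role in ventricle_roles) {
    target <- as.integer(round((1 + g) * cnt_of[[role]]))
    mask <- vox == lab_of[[role]]
    new_mask <- grow_to_count(mask, vox == 0L, target)
    vox[new_mask & !mask] <- lab_of[[role]]
  }
  new_counts <- vapply(phantom_roles,
                       function(role) sum(vox == lab_of[[role]]), numeric(1))
  new_truth <- tibble(role = phantom_roles,
                      label = as.integer(lab_of[phantom_roles]),
                      voxel_count = as.integer(new_counts),
                      volume_mm3 = unname(new_counts) *
                        prod(phantom$volume$spacing),
                      applied_loss_fraction = f,
                      applied_gain_fraction = g)
  structure(list(volume = label_volume(vox, phantom$volume$spacing),
                 truth = new_truth, spec = phantom$spec),
            class = "yrrta_phantom")
}
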