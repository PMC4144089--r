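test_that("reference slice maximizes third-ventricle area among candidate slices", {
  vol <- reference_slice_fixture()
  sel <- select_reference_slice(vol)
  # independent oracle: exhaustive per-slice scan of the fixture
  per_slice <- vapply(seq_len(dim(vol$voxels)[3]), function(z) {
    sl <- vol$voxels[, , z]
    if (any(sl == 1L) && any(sl == 2L)) sum(sl == 5L) else -1L
  }, integer(1))
  expect_equal(sel$slice_index, which.max(per_slice))
  expect_equal(sel$slice_index, 3L)
  expect_equal(sel$third_ventricle_area_mm2, 3)
  expect_true(sel$both_thalami_present)
})

test_that("a single both-thalami slice wins regardless of third-ventricle area", {
  vol <- tiny_volume(c(7, 7, 6))
  vol <- place(vol, 1, 6, 3, 2)
  vol <- place(vol, 2, 2, 3, 2)        # only slice 2 has both thalami
  vol <- place(vol, 5, 4, 3:5, 5)      # big third ventricle elsewhere
  expect_equal(select_reference_slice(vol)$slice_index, 2L)
})

test_that("ties break toward the most inferior slice", {
  vol <- tiny_volume(c(7, 7, 6))
  for (z in c(2, 4)) {
    vol <- place(vol, 1, 6, 3, z)
    vol <- place(vol, 2, 2, 3, z)
    vol <- place(vol, 5, 4, 3:4, z)    # identical maximal area on 2 and 4
  }
  expect_equal(select_reference_slice(vol)$slice_index, 2L)
})

test_that("selection errors name the missing structure", {
  vol <- tiny_volume()
  vol <- place(vol, 2, 2, 3, 2)
  expect_error(select_reference_slice(vol), "right thalamus",
               class = "yrrta_selection_error")
  # thalami present on disjoint slices only
  vol2 <- tiny_volume()
  vol2 <- place(vol2, 1, 6, 3, 2)
  vol2 <- place(vol2, 2, 2, 3, 4)
  expect_error(select_reference_slice(vol2), "common slice",
               class = "yrrta_selection_error")
})

test_that("selection is invariant to padding background slices above/below", {
  vol <- reference_slice_fixture()
  padded <- label_volume(
    abind_slices <- array(0L, dim(vol$voxels) + c(0, 0, 4)),
    vol$spacing)
  padded$voxels[, , 3:8] <- vol$voxels
  sel0 <- select_reference_slice(vol)
  sel1 <- select_reference_slice(padded)
  expect_equal(sel1$slice_index, sel0$slice_index + 2L)
  expect_equal(sel1$third_ventricle_area_mm2, sel0$third_ventricle_area_mm2)
})

test_that("region_area counts pixels times in-plane pixel area", {
  vol <- tiny_volume(c(6, 6, 3), spacing = c(1, 1, 4))
  vol <- place(vol, 1, rep(1:5, 2), rep(1:2, each = 5), 2)  # 10 pixels
  expect_equal(region_area(vol, 1, 2), 10)
  half <- label_volume(vol$voxels, spacing = c(0.5, 0.5, 4))
  expect_equal(region_area(half, 1, 2), 2.5)
  expect_equal(region_area(vol, integer(0), 2), 0)
  expect_equal(region_area(vol, 1, 1), 0)
  expect_error(region_area(vol, 1, 9), class = "yrrta_bounds_error")
  expect_error(region_area(vol, 1, 0), class = "yrrta_bounds_error")
})

test_that("region_volume counts voxels times voxel volume", {
  vox <- array(0L, c(12, 12, 12)); vox[2:11, 2:11, 2:11] <- 1L
  vol <- label_volume(vox, spacing = c(1, 1, 1))
  expect_equal(region_volume(vol, 1), 1000)
  expect_equal(region_volume(vol, 7), 0)
  aniso <- label_volume(vox, spacing = c(0.5, 0.5, 2))
  expect_equal(region_volume(aniso, 1), 1000 * 0.5)
})

test_that("areas and volumes are additive over disjoint label sets", {
  vol <- reference_slice_fixture()
  s <- 3L
  expect_equal(region_area(vol, c(1, 2), s),
               region_area(vol, 1, s) + region_area(vol, 2, s))
  expect_equal(region_volume(vol, c(1, 2, 5)),
               region_volume(vol, 1) + region_volume(vol, 2) +
                 region_volume(vol, 5))
})

test_that("scaling spacing by k scales areas by k^2 and volumes by k^3", {
  vol <- reference_slice_fixture()
  k <- 1.7
  scaled <- label_volume(vol$voxels, vol$spacing * k)
  expect_equal(region_area(scaled, 5, 3), k^2 * region_area(vol, 5, 3))
  expect_equal(region_volume(scaled, 5), k^3 * region_volume(vol, 5))
})

test_that("summing slice areas times slice thickness equals the volume", {
  ph <- generate_phantom(phantom_spec())
  vol <- ph$volume
  for (lab in c(1L, 3L, 5L)) {
    cav <- sum(vapply(seq_len(dim(vol$voxels)[3]), function(z) {
      region_area(vol, lab, z)
    }, numeric(1))) * vol$spacing[3]
    expect_equal(cav, region_volume(vol, lab))
  }
})

test_that("2D extraction measures the selected slice and unions ventricles", {
  ph <- generate_phantom(phantom_spec())
  m <- extract_measurements_2d(ph$volume)
  s <- m$slice_index
  # voxel-count oracle on the generated phantom
  sl <- ph$volume$voxels[, , s]
  px <- prod(ph$volume$spacing[1:2])
  expect_equal(m$area_A, sum(sl == 1L) * px)
  expect_equal(m$area_A_prime, sum(sl == 2L) * px)
  expect_equal(m$area_B, sum(sl %in% 3:5) * px)
  # disjoint-union additivity of B
  expect_equal(m$area_B,
               region_area(ph$volume, 3, s) + region_area(ph$volume, 4, s) +
                 region_area(ph$volume, 5, s))
  # slice override to a ventricle-free slice gives area_B = 0
  m1 <- extract_measurements_2d(ph$volume, slice_override = 1)
  expect_equal(m1$area_B, 0)
  expect_equal(m1$slice_index, 1L)
})

test_that("3D extraction equals ground truth and warns on absent structures", {
  ph <- generate_phantom(phantom_spec())
  m <- extract_measurements_3d(ph$volume)
  truth <- ph$truth
  vv <- prod(ph$volume$spacing)
  expect_equal(m$vol_A, truth$voxel_count[truth$role == "thalamus_right"] * vv)
  expect_equal(m$vol_D,
               truth$voxel_count[truth$role == "third_ventricle"] * vv)
  # absent third ventricle: 0 with a warning
  vox <- ph$volume$voxels
  vox[vox == 5L] <- 0L
  noD <- label_volume(vox, ph$volume$spacing)
  expect_warning(mD <- extract_measurements_3d(noD),
                 class = "yrrta_absent_structure_warning")
  expect_equal(mD$vol_D, 0)
})

test_that("swapping thalamus labels with a swapped label map is a no-op", {
  ph <- generate_phantom(phantom_spec())
  vox <- ph$volume$voxels
  swapped <- vox
  swapped[vox == 1L] <- 2L
  swapped[vox == 2L] <- 1L
  vol_sw <- label_volume(swapped, ph$volume$spacing)
  lm_sw <- label_map(thalamus_right = 2, thalamus_left = 1)
  expect_equal(extract_measurements_3d(vol_sw, lm_sw),
               extract_measurements_3d(ph$volume))
})

test_that("face-adjacent thalamus labels trigger the midline warning", {
  vol <- tiny_volume()
  vol <- place(vol, 1, 4, 3, 2)
  vol <- place(vol, 2, 3, 3, 2)  # touches label 1 across a face
  vol <- place(vol, 5, 4, 4, 2)
  expect_warning(extract_measurements_2d(vol),
                 class = "yrrta_midline_warning")
  # separated thalami: no warning
  vol2 <- reference_slice_fixture()
  expect_silent(extract_measurements_2d(vol2))
})

test_that("months_between uses the mean Gregorian month", {
  expect_equal(months_between("2020-01-01", "2021-01-01"), 366 / 30.4375)
  expect_error(months_between("2021-01-01", "2020-01-01"),
               class = "yrrta_validation_error")
})
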