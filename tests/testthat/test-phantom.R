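test_that("ground truth is exactly voxel count times voxel volume", {
  ph <- generate_phantom(phantom_spec())
  vv <- prod(ph$volume$spacing)
  expect_identical(ph$truth$volume_mm3, ph$truth$voxel_count * vv)
  # and the morphometry module recovers it exactly
  m <- extract_measurements_3d(ph$volume)
  tr <- setNames(ph$truth$volume_mm3, ph$truth$role)
  expect_identical(m$vol_A, tr[["thalamus_right"]])
  expect_identical(m$vol_A_prime, tr[["thalamus_left"]])
  expect_identical(m$vol_C, tr[["lateral_ventricle_right"]])
  expect_identical(m$vol_C_prime, tr[["lateral_ventricle_left"]])
  expect_identical(m$vol_D, tr[["third_ventricle"]])
})

test_that("rasterized ellipsoid volume is accurate and converges under refinement", {
  analytic <- 4 / 3 * pi * 10 * 8 * 6
  errs <- vapply(c(2, 1, 0.5), function(h) {
    ph <- generate_phantom(phantom_spec(grid_shape = round(c(64, 56, 44) / h),
                                        spacing = h,
                                        thalamus_semi_axes = c(10, 8, 6)))
    v <- ph$truth$volume_mm3[ph$truth$role == "thalamus_right"]
    abs(v - analytic) / analytic
  }, numeric(1))
  expect_lt(errs[3], 0.02)             # within 2% at 0.5 mm isotropic
  expect_true(all(diff(errs) < 0))     # monotone 3-level refinement
})

test_that("phantom generation is deterministic and labels are disjoint by construction", {
  a <- generate_phantom(phantom_spec())
  b <- generate_phantom(phantom_spec())
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth, b$truth)
  # five distinct labels plus background; counts match the truth table
  tab <- table(a$volume$voxels)
  expect_setequal(as.integer(names(tab)), 0:5)
  for (i in 1:5) {
    expect_equal(unname(tab[[as.character(i)]]),
                 a$truth$voxel_count[a$truth$label == i])
  }
})

test_that("overlapping structures abort with the colliding pair named", {
  expect_error(generate_phantom(phantom_spec(thalamus_offset_x = 0)),
               "thalamus_right / thalamus_left|overlap",
               class = "yrrta_spec_error")
})

test_that("zero change is the identity", {
  base <- generate_phantom(phantom_spec())
  same <- apply_change(base, 0, 0)
  expect_identical(same$volume$voxels, base$volume$voxels)
})

test_that("apply_change hits shrink and growth targets to the voxel", {
  base <- generate_phantom(phantom_spec(spacing = 1,
                                        grid_shape = c(64, 56, 44)))
  n0 <- setNames(base$truth$voxel_count, base$truth$role)
  fu <- apply_change(base, 0.05, 0.03)
  n1 <- setNames(fu$truth$voxel_count, fu$truth$role)
  # direct recount against the bisection/ranking targets
  for (role in c("thalamus_right", "thalamus_left")) {
    expect_equal(n1[[role]], round(0.95 * n0[[role]]))
  }
  for (role in c("lateral_ventricle_right", "lateral_ventricle_left",
                 "third_ventricle")) {
    expect_equal(n1[[role]], round(1.03 * n0[[role]]))
  }
  # truth recount agrees with an independent tabulation of the volume
  tab <- table(fu$volume$voxels)
  for (i in 1:5) {
    expect_equal(unname(tab[[as.character(i)]]),
                 fu$truth$voxel_count[fu$truth$label == i])
  }
})

test_that("shrinking erodes from the boundary inward", {
  base <- generate_phantom(phantom_spec())
  fu <- apply_change(base, 0.10, 0)
  # the follow-up thalamus is a subset of the baseline thalamus
  expect_true(all(base$volume$voxels[fu$volume$voxels == 1L] == 1L))
  expect_true(all(base$volume$voxels[fu$volume$voxels == 2L] == 2L))
})

test_that("ventricles grow only into background and structures stay disjoint", {
  base <- generate_phantom(phantom_spec())
  fu <- apply_change(base, 0.05, 0.10)
  grown <- fu$volume$voxels %in% 3:5 & !(base$volume$voxels %in% 3:5)
  # every newly ventricular voxel was background after thalamic shrinkage,
  # i.e. never a surviving thalamus voxel
  expect_false(any(fu$volume$voxels[grown] %in% 1:2))
  surviving_thal <- fu$volume$voxels %in% 1:2
  expect_false(any(grown & surviving_thal))
  # each voxel carries at most one role at the follow-up timepoint
  expect_true(all(fu$volume$voxels %in% 0:5))
})

test_that("measured volumes recover applied loss fractions", {
  base <- generate_phantom(phantom_spec(spacing = 1,
                                        grid_shape = c(64, 56, 44)))
  m0 <- extract_measurements_3d(base$volume)
  vv <- prod(base$volume$spacing)
  n0 <- base$truth$voxel_count[base$truth$role == "thalamus_right"] +
    base$truth$voxel_count[base$truth$role == "thalamus_left"]
  for (f in c(0.01, 0.03, 0.05)) {
    fu <- apply_change(base, f, 0)
    m1 <- extract_measurements_3d(fu$volume)
    recovered <- ((m0$vol_A + m0$vol_A_prime) -
                    (m1$vol_A + m1$vol_A_prime)) /
      (m0$vol_A + m0$vol_A_prime)
    # within one voxel-equivalent of the applied fraction
    expect_lt(abs(recovered - f), vv / (n0 * vv) + 1e-12)
    # and yr_ta is strictly positive for any positive applied loss
    expect_gt(yr_ta(m0$vol_A + m0$vol_A_prime,
                    m1$vol_A + m1$vol_A_prime, 12), 0)
  }
})

test_that("unreachable growth targets report the achievable bound", {
  # a tiny closed box leaves no background for a huge ventricle gain
  spec <- phantom_spec()
  base <- generate_phantom(spec)
  expect_error(apply_change(base, 0, 50),
               "achievable", class = "yrrta_change_error")
  expect_error(apply_change(base, 0.9999, 0),
               class = "yrrta_change_error")
  expect_error(apply_change(base, 1.2, 0),
               class = "yrrta_validation_error")
  expect_error(apply_change(base, -0.1, 0),
               class = "yrrta_validation_error")
})
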