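# Small fixtures built in code at test time.

# A hand-buildable label volume: explicit voxel placements, no geometry.
tiny_volume <- function(dims = c(6, 6, 5), spacing = c(1, 1, 1)) {
  vox <- array(0L, dims)
  label_volume(vox, spacing)
}

place <- function(vol, label, x, y, z) {
  vol$voxels[cbind(x, y, z)] <- as.integer(label)
  vol
}

# A volume with both thalami on slices 2:4 and a third ventricle whose
# cross-section peaks (3 voxels) on slice 3.
reference_slice_fixture <- function() {
  vol <- tiny_volume(c(7, 7, 6))
  for (z in 2:4) {
    vol <- place(vol, 1, c(6, 6), c(3, 4), z)  # right thalamus
    vol <- place(vol, 2, c(2, 2), c(3, 4), z)  # left thalamus
  }
  vol <- place(vol, 5, 4, 4, 2)
  vol <- place(vol, 5, 4, 3:5, 3)              # peak cross-section
  vol <- place(vol, 5, 4, 4, 4)
  vol
}

# Independent plain-arithmetic oracle for the three rate formulas;
# deliberately coded apart from the package implementation.
oracle_rates <- function(ta1, ta2, ve1, ve2, months, factor = 120) {
  d_ta <- ta1 - ta2
  d_ve <- ve2 - ve1
  list(yrTA = d_ta * factor / months,
       yrVE = d_ve * factor / months,
       yrRTA_printed = if (d_ve == 0) NA_real_ else
         d_ta * factor / (d_ve * months),
       yrRTA_pure = if (d_ve == 0) NA_real_ else d_ta / d_ve)
}

random_pairs <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    A1 = runif(n, 100, 4000), A_prime1 = runif(n, 100, 4000),
    B1 = runif(n, 500, 9000),
    A2 = runif(n, 100, 4000), A_prime2 = runif(n, 100, 4000),
    B2 = runif(n, 500, 9000),
    months = runif(n, 3, 36))
}

write_measurement_csv <- function(tbl, path = withr::local_tempfile(
                                    fileext = ".csv",
                                    .local_envir = parent.frame())) {
  readr::write_csv(tbl, path)
  path
}
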