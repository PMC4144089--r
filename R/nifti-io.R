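#' Read a NIfTI segmentation label volume
#'
#' Reads a NIfTI-1/NIfTI-2 file containing integer structure labels,
#' takes the voxel spacing from the header, and normalizes the grid to
#' the canonical RAS orientation (third axis inferior-to-superior) using
#' the header's qform/sform, so that "axial slice k" means the same
#' thing for every input. Reorientation only permutes and flips axes;
#' it never changes label values or per-label voxel counts. Files
#' without orientation metadata are assumed to already be in canonical
#' order.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [label_volume()].
#' @seealso [write_label_volume()]
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "yrrta_io_error")
  }
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path, internal = FALSE)),
                  error = function(e) {
                    abort(paste0("Not a readable NIfTI file: ", path,
                                 " (", conditionMessage(e), ")"),
                          class = "yrrta_format_error")
                  })
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0L || hdr$sform_code > 0L) {
    RNifti::orientation(img) <- "RAS"
  }
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) {
    abort("Expected a 3D volume.", class = "yrrta_format_error")
  }
  arr <- array(as.vector(arr), d)  # drop image attributes
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    abort("Header voxel dimensions must be positive.",
          class = "yrrta_header_error")
  }
  if (any(arr != round(arr))) {
    abort("Volume contains non-integer values; expected a label volume.",
          class = "yrrta_data_error")
  }
  label_volume(arr, spacing = sp)
}

#' Write a label volume to NIfTI
#'
#' Writes the labels as 16-bit integers with the spacing recorded in
#' both the pixdim field and a diagonal qform, so a subsequent
#' [read_label_volume()] recovers voxels and spacing exactly.
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  if (!dir.exists(dirname(path))) {
    abort(paste0("Directory does not exist: ", dirname(path)),
          class = "yrrta_io_error")
  }
  d <- dim(vol$voxels)
  dt <- if (max(vol$voxels) > 32767L) 8L else 4L  # int32 vs int16
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, d, 1L, 1L, 1L, 1L),
    pixdim = c(1, vol$spacing, 1, 1, 1, 1),
    datatype = dt))
  img <- RNifti::asNifti(vol$voxels, reference = hdr)
  RNifti::qform(img) <- structure(diag(c(vol$spacing, 1)), code = 2L)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) {
             abort(paste0("Cannot write NIfTI file: ", path,
                          " (", conditionMessage(e), ")"),
                   class = "yrrta_io_error")
           })
  invisible(path)
}
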