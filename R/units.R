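#' Unit conversions between voxels, angstroms, and nanometers
#'
#' All world coordinates in granametrics are nanometers. Tomographic data mix
#' angstrom pixel sizes, binned voxel indices, and nanometer measurements;
#' these helpers perform the conversions at the I/O boundary so that no other
#' code needs to carry unit factors.
#'
#' @param voxels number of voxels (may be fractional).
#' @param pixel_size_ang acquisition pixel size in angstroms (unbinned).
#' @param binning integer binning factor of the grid the voxels refer to
#'   (e.g. 4 for a bin4 tomogram).
#' @return length in nanometers.
#' @examples
#' voxels_to_nm(21, pixel_size_ang = 3.52, binning = 4) # 29.568 nm
#' @export
voxels_to_nm <- function(voxels, pixel_size_ang, binning = 1L) {
  stopifnot(pixel_size_ang > 0, binning >= 1)
  voxels * ang_to_nm(pixel_size_ang) * binning
}

#' @rdname voxels_to_nm
#' @param nm length in nanometers.
#' @export
nm_to_voxels <- function(nm, pixel_size_ang, binning = 1L) {
  stopifnot(pixel_size_ang > 0, binning >= 1)
  nm / (ang_to_nm(pixel_size_ang) * binning)
}

#' @rdname voxels_to_nm
#' @param ang length in angstroms.
#' @export
ang_to_nm <- function(ang) ang / 10

#' @rdname voxels_to_nm
#' @export
nm_to_ang <- function(nm) nm * 10
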