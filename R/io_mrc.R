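#' Read an MRC2014 volume
#'
#' Reads modes 0 (int8), 1 (int16), 2 (float32), 6 (uint16) and 12 (float16 is
#' not supported). The voxel size is taken from the cell dimensions
#' (`xlen/mx`, in angstroms on disk) and converted to nanometers; a zero or
#' missing header voxel size is an error unless `pixel_size_ang` overrides it.
#' MRC stores x fastest; the returned array is indexed `[x, y, z]`.
#'
#' @param path file path.
#' @param pixel_size_ang optional override of the header pixel size, in
#'   angstroms per voxel.
#' @return a [density_volume]; the header origin (angstroms) becomes the
#'   world origin in nm.
#' @export
read_mrc <- function(path, pixel_size_ang = NULL) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  mxyz <- hdr_ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 49 * 4)  # words 50-52: origin
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 23 * 4)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.null(pixel_size_ang)) {
    if (any(mxyz <= 0) || any(cella <= 0))
      stop("MRC header has no usable voxel size (cella/mx zero); ",
           "supply pixel_size_ang")
    vs_ang <- cella / mxyz
  } else {
    vs_ang <- rep_len(pixel_size_ang, 3L)
  }
  if (any(vs_ang <= 0)) stop("voxel size must be > 0")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  arr <- array(as.numeric(vals), dim = c(nx, ny, nz))
  density_volume(arr, voxel_size = ang_to_nm(vs_ang),
                 origin = ang_to_nm(orig))
}

#' Write an MRC2014 volume
#'
#' Integer-valued volumes whose range fits int8 are written as mode 0
#' (lossless for binary masks); everything else as mode 2 float32.
#'
#' @param vol a [density_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$values)
  vals <- vol$values
  is_int8 <- all(vals == round(vals)) && min(vals) >= -128 && max(vals) <= 127
  mode <- if (is_int8) 0L else 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(d, mode))            # nx ny nz mode
  wi(c(0, 0, 0))            # nxstart
  wi(d)                     # mx my mz
  wf(nm_to_ang(vol$voxel_size) * d)  # cella (angstrom)
  wf(c(90, 90, 90))         # cellb
  wi(c(1, 2, 3))            # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))  # dmin dmax dmean
  wi(c(1, 0))               # ispg, nsymbt
  wi(rep(0L, 25))           # extra words 25..49
  wf(nm_to_ang(vol$origin)) # origin words 50-52 (angstrom)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(vals))       # rms
  wi(0L)                    # nlabl
  writeBin(raw(800), con)   # labels
  if (mode == 0L) {
    writeBin(as.integer(vals), con, size = 1)
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  invisible(path)
}
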