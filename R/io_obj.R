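#' Read a Wavefront OBJ mesh
#'
#' Vertices are taken as world nanometers. Faces with more than three
#' vertices are triangulated fan-wise with a warning. Duplicate vertices are
#' preserved as stored. Indices are 1-based on disk (OBJ standard) and
#' 1-based in memory.
#'
#' @param path file path.
#' @return a [tri_mesh].
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop("OBJ file ", path, " has no vertices or no faces")
  v <- matrix(as.numeric(unlist(lapply(strsplit(vl, "\\s+"),
                                       function(p) p[2:4]))),
              ncol = 3, byrow = TRUE)
  fan <- FALSE
  faces <- lapply(strsplit(fl, "\\s+"), function(p) {
    idx <- as.integer(sub("/.*$", "", p[-1]))
    if (length(idx) == 3L) return(matrix(idx, 1, 3))
    fan <<- TRUE
    cbind(idx[1], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  })
  if (fan) warning("non-triangular OBJ faces triangulated fan-wise")
  tri_mesh(v, do.call(rbind, faces))
}

#' Write a Wavefront OBJ mesh
#'
#' @param mesh a [tri_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# granametrics triangle mesh (nm)", con)
  writeLines(sprintf("v %.6f %.6f %.6f",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}
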