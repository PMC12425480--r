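#' Read a STAR particle table
#'
#' Parses the first `loop_` block of a STAR file into a data frame (one row
#' per particle). Column names follow the RELION convention
#' (`_rlnCoordinateX` etc.); `aliases` maps the semantic roles onto column
#' names so other dialects can be read. Coordinates on disk are voxel
#' coordinates at `pixel_size_nm` per voxel and are converted to world
#' nanometer columns `x`, `y`, `z`; all other columns are preserved verbatim.
#'
#' @param path file path.
#' @param pixel_size_nm voxel size (nm) used to scale coordinates.
#' @param aliases named list with entries `x`, `y`, `z` (required roles),
#'   `angle`, `class`, `membrane` (optional roles), each a character vector
#'   of acceptable column names, first match wins.
#' @return a `particle_set` data frame with columns `x`, `y`, `z` (nm),
#'   `angle` (degrees in \[0, 360)), `class`, `membrane`, plus any extra STAR
#'   columns prefixed `star.`.
#' @export
read_star <- function(path, pixel_size_nm = 1,
                      aliases = star_default_aliases()) {
  lines <- readLines(path, warn = FALSE)
  li <- grep("^\\s*loop_\\s*$", lines)
  if (length(li) == 0) stop("no loop_ block found in ", path)
  i <- li[1] + 1L
  cols <- character(0)
  while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
    cols <- c(cols, sub("^\\s*(_\\S+).*$", "\\1", lines[i]))
    i <- i + 1L
  }
  if (length(cols) == 0) stop("loop_ block in ", path, " declares no columns")
  rows <- character(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(data_|loop_|#)", ln)) break
    rows <- c(rows, ln)
    i <- i + 1L
  }
  if (length(rows) == 0) {
    tab <- as.data.frame(matrix(character(0), 0, length(cols)),
                         stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(text = rows, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = seq_along(cols))
  }
  names(tab) <- cols
  pick <- function(role) {
    hit <- intersect(aliases[[role]], cols)
    if (length(hit)) hit[1] else NA_character_
  }
  cx <- pick("x"); cy <- pick("y"); cz <- pick("z")
  if (any(is.na(c(cx, cy, cz))))
    stop("STAR file ", path, " lacks coordinate columns; found: ",
         paste(cols, collapse = ", "))
  n <- nrow(tab)
  ca <- pick("angle"); cc <- pick("class"); cm <- pick("membrane")
  out <- data.frame(
    x = as.numeric(tab[[cx]]) * pixel_size_nm,
    y = as.numeric(tab[[cy]]) * pixel_size_nm,
    z = as.numeric(tab[[cz]]) * pixel_size_nm,
    angle = if (!is.na(ca)) as.numeric(tab[[ca]]) %% 360 else rep(0, n),
    class = if (!is.na(cc)) as.character(tab[[cc]]) else rep("unknown", n),
    membrane = if (!is.na(cm)) as.character(tab[[cm]]) else rep("m1", n),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(cols, c(cx, cy, cz, ca, cc, cm))
  for (e in extra) out[[paste0("star.", sub("^_", "", e))]] <- tab[[e]]
  particle_set(out)
}

#' @rdname read_star
#' @export
star_default_aliases <- function() {
  list(x = c("_rlnCoordinateX", "_CoordinateX", "_x"),
       y = c("_rlnCoordinateY", "_CoordinateY", "_y"),
       z = c("_rlnCoordinateZ", "_CoordinateZ", "_z"),
       angle = c("_rlnAnglePsi", "_rlnAngleRot", "_psi", "_angle"),
       class = c("_rlnClassNumber", "_class", "_granClass"),
       membrane = c("_rlnMicrographName", "_membrane", "_granMembrane"))
}

#' Write a STAR particle table
#'
#' World nm coordinates are converted back to voxel units; the written
#' columns are the RELION-style primary aliases. Round-trips with
#' [read_star()] preserve coordinates to better than 1e-4 nm.
#'
#' @param particles a `particle_set` (see [particle_set()]).
#' @param path output path.
#' @param pixel_size_nm voxel size (nm) used to scale coordinates.
#' @return `path`, invisibly.
#' @export
write_star <- function(particles, path, pixel_size_nm = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_",
               "_rlnCoordinateX #1", "_rlnCoordinateY #2",
               "_rlnCoordinateZ #3", "_rlnAnglePsi #4",
               "_granClass #5", "_granMembrane #6"), con)
  if (nrow(particles) > 0) {
    writeLines(sprintf("%.6f\t%.6f\t%.6f\t%.4f\t%s\t%s",
                       particles$x / pixel_size_nm,
                       particles$y / pixel_size_nm,
                       particles$z / pixel_size_nm,
                       particles$angle,
                       particles$class, particles$membrane), con)
  }
  writeLines("", con)
  invisible(path)
}
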