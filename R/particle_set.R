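#' Particle set bound to a membrane
#'
#' A data frame of particle records: world position (nm), in-plane
#' orientation (degrees in \[0, 360)), class label (`PSII`, `cytb6f`,
#' `unknown`, or any user class), membrane id, and a `clipped` flag marking
#' particles close enough to the membrane boundary that their footprint may
#' be truncated. Clipped particles are kept in concentration statistics and
#' flagged so that nearest-neighbor sources can exclude them.
#'
#' @param df data frame with at least columns `x`, `y`, `z`; missing
#'   `angle`, `class`, `membrane`, `clipped` columns are filled with
#'   defaults (0, "unknown", "m1", FALSE).
#' @return a data frame of class `particle_set`.
#' @export
particle_set <- function(df = data.frame(x = numeric(0), y = numeric(0),
                                         z = numeric(0))) {
  df <- as.data.frame(df)
  for (need in c("x", "y", "z"))
    if (is.null(df[[need]])) stop("particle_set needs column ", need)
  n <- nrow(df)
  if (is.null(df$angle)) df$angle <- rep(0, n)
  df$angle <- as.numeric(df$angle) %% 360
  if (is.null(df$class)) df$class <- rep("unknown", n)
  if (is.null(df$membrane)) df$membrane <- rep("m1", n)
  if (is.null(df$clipped)) df$clipped <- rep(FALSE, n)
  class(df) <- c("particle_set", "data.frame")
  df
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$class)
    cat(": ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "), sep = "")
    if (any(x$clipped)) cat(sprintf(" (%d clipped)", sum(x$clipped)))
  }
  cat("\n")
  invisible(x)
}

particle_positions <- function(particles) {
  cbind(particles$x, particles$y, particles$z)
}
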