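#' Create a particle set
#'
#' A particle set holds integer 0-based voxel coordinates `(x, y, z)` with a
#' non-negative weight per particle, as a tibble with columns `x`, `y`, `z`,
#' `weight` plus `feature_name` / `source_volume` attributes.
#'
#' @param x,y,z integer voxel coordinates (0-based).
#' @param weight per-particle non-negative weights (default 1).
#' @param feature_name name of the segmented feature.
#' @param source_volume optional path of the volume the particles came from.
#' @param bounds optional `c(nx, ny, nz)`; when given, coordinates are checked
#'   to lie inside `[0, bounds)`.
#' @return A tibble of class `particle_set`.
#' @export
particle_set <- function(x = integer(), y = integer(), z = integer(),
                         weight = rep(1, length(x)), feature_name = "feature",
                         source_volume = NA_character_, bounds = NULL) {
  if (!(length(x) == length(y) && length(y) == length(z) &&
        length(z) == length(weight))) {
    stop_fmt("x, y, z and weight must have equal lengths")
  }
  if (any(weight < 0)) stop_fmt("particle weights must be non-negative")
  if (length(x) && any(c(x, y, z) != floor(c(x, y, z)))) {
    stop_fmt("particle coordinates must be integers")
  }
  if (!is.null(bounds) && length(x)) {
    if (any(x < 0 | y < 0 | z < 0 | x >= bounds[1] | y >= bounds[2] |
            z >= bounds[3])) {
      stop_fmt("particle coordinates outside volume bounds %s",
               paste(bounds, collapse = "x"))
    }
  }
  out <- tibble::tibble(x = as.integer(x), y = as.integer(y),
                        z = as.integer(z), weight = as.numeric(weight))
  attr(out, "feature_name") <- feature_name
  attr(out, "source_volume") <- source_volume
  class(out) <- c("particle_set", class(out))
  out
}

#' Write particle coordinates as tab-separated text or STAR
#'
#' The `tsv` dialect writes one `x<TAB>y<TAB>z` line per particle with no
#' header. The `star` dialect writes a minimal RELION-style coordinate block
#' (`_rlnCoordinateX/Y/Z`). Coordinates are written 0-based by default; some
#' extraction tools expect 1-based indexing, in which case set
#' `one_based = TRUE`.
#'
#' @param particles a [particle_set()].
#' @param path output path.
#' @param dialect `"tsv"` or `"star"`.
#' @param one_based add 1 to every coordinate on write.
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path, dialect = c("tsv", "star"),
                            one_based = FALSE) {
  dialect <- match.arg(dialect)
  off <- if (one_based) 1L else 0L
  xyz <- cbind(particles$x + off, particles$y + off, particles$z + off)
  if (dialect == "tsv") {
    lines <- if (nrow(xyz)) apply(xyz, 1, paste, collapse = "\t") else character()
  } else {
    lines <- c("", "data_particles", "", "loop_",
               "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3",
               if (nrow(xyz)) apply(xyz, 1, paste, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read particle coordinates written by [write_particles()]
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"star"`.
#' @param feature_name feature name to attach.
#' @return A [particle_set()] (weights are 1; the text formats carry none).
#' @export
read_particles <- function(path, dialect = c("tsv", "star"),
                           feature_name = "feature") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "star") {
    body <- grep("^\\s*-?[0-9]", lines, value = TRUE)
  } else {
    body <- lines[nzchar(lines)]
  }
  if (!length(body)) {
    return(particle_set(feature_name = feature_name, source_volume = path))
  }
  m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  particle_set(m[, 1], m[, 2], m[, 3], feature_name = feature_name,
               source_volume = path)
}
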