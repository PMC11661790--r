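#' Create a triangle mesh
#'
#' @param vertices numeric matrix `n x 3`, vertex positions in Angstrom.
#' @param faces integer matrix `m x 3` of 1-based vertex indices (triangles).
#' @param feature_name name of the feature the mesh represents.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices = matrix(numeric(), 0, 3),
                     faces = matrix(integer(), 0, 3),
                     feature_name = "feature") {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (length(vertices) && ncol(vertices) != 3L) {
    stop_fmt("vertices must be an n x 3 matrix")
  }
  if (length(faces) && ncol(faces) != 3L) {
    stop_fmt("faces must be an m x 3 matrix of triangles")
  }
  if (length(faces)) {
    storage.mode(faces) <- "integer"
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop_fmt("face indices must reference existing vertices (1..%d)",
               nrow(vertices))
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 feature_name = feature_name),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> '%s': %d vertices, %d faces\n",
              x$feature_name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write a mesh as Wavefront OBJ
#'
#' Emits `v x y z` lines followed by `f i j k` lines with 1-based indices.
#' The mesh is validated before anything is written.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) &&
      (min(mesh$faces) < 1L || max(mesh$faces) > nrow(mesh$vertices))) {
    stop_fmt("mesh face references a missing vertex; nothing written")
  }
  vlines <- if (nrow(mesh$vertices)) {
    sprintf("v %.6g %.6g %.6g", mesh$vertices[, 1], mesh$vertices[, 2],
            mesh$vertices[, 3])
  } else character()
  flines <- if (nrow(mesh$faces)) {
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  } else character()
  writeLines(c(vlines, flines), path)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Minimal reader for the subset [write_mesh_obj()] emits (`v` and `f` lines;
#' `f` entries may carry `/`-separated texture/normal indices, which are
#' dropped).
#'
#' @param path file path.
#' @param feature_name feature name to attach.
#' @return A [tri_mesh()].
#' @export
read_mesh_obj <- function(path, feature_name = "feature") {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- if (length(vl)) {
    do.call(rbind, lapply(strsplit(sub("^v ", "", vl), "\\s+"), as.numeric))
  } else matrix(numeric(), 0, 3)
  f <- if (length(fl)) {
    do.call(rbind, lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(p) {
      as.integer(sub("/.*$", "", p))
    }))
  } else matrix(integer(), 0, 3)
  tri_mesh(v, f, feature_name = feature_name)
}
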