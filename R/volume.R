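#' Create a 3D volume
#'
#' The central data container: a 3D scalar grid with an isotropic voxel size.
#' Arrays are dimensioned `c(nx, ny, nz)` so `data[x + 1, y + 1, z + 1]`
#' addresses the 0-based voxel `(x, y, z)`; `z` is the slice index.
#'
#' @param data numeric 3D array, dim `c(nx, ny, nz)`.
#' @param voxel_size voxel edge length in Angstrom; must be `> 0`.
#' @param origin length-3 numeric, volume origin in Angstrom.
#' @return An object of class `volume3d` with fields `data`, `voxel_size`,
#'   `origin`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 4)), voxel_size = 10)
#' dim(v)
#' @export
volume3d <- function(data, voxel_size = 10, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_fmt("`data` must be a 3D array (got %s dims)",
             paste(length(dim(data)), collapse = "x"))
  }
  if (any(dim(data) < 1L)) stop_fmt("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop_fmt("`voxel_size` must be a single positive number")
  }
  if (length(origin) != 3L) stop_fmt("`origin` must have length 3")
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "volume3d"
  )
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %.3g A/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

as_volume_like <- function(data, template) {
  volume3d(data, voxel_size = template$voxel_size, origin = template$origin)
}

# Validate that a volume is a prediction volume (all values in [0, 1]).
check_prediction_volume <- function(v, what = "prediction volume") {
  r <- range(v$data)
  if (r[1] < 0 || r[2] > 1) {
    stop_fmt("%s must have all values in [0, 1] (range [%.4g, %.4g])",
             what, r[1], r[2])
  }
  invisible(v)
}
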