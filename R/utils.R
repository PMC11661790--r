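# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up to integer; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# nm -> pixels given a pixel size in Angstrom (1 nm = 10 A)
nm_to_px <- function(nm, pixel_size) nm * 10 / pixel_size

# voxel count -> nm^3 given pixel size in Angstrom
voxels_to_nm3 <- function(n_voxels, pixel_size) n_voxels * (pixel_size / 10)^3

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Per-patch intensity normalization: zero mean, unit variance. A flat patch
# (zero variance) maps to all zeros rather than dividing by ~0.
normalize_patch <- function(m) {
  mu <- mean(m)
  s <- stats::sd(as.vector(m))
  if (!is.finite(s) || s < 1e-9) {
    return(array(0, dim = dim(m)))
  }
  (m - mu) / s
}
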