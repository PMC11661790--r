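# Particle picking: threshold -> distance transform -> watershed -> filters.

#' Particle picking configuration
#'
#' @param threshold binarization level in `(0, 1]` applied to the prediction
#'   volume.
#' @param min_volume_nm3 groups smaller than this physical volume are
#'   discarded as dust.
#' @param min_spacing_nm minimum centroid-to-centroid distance between
#'   retained particles; of two closer groups the lower-weight one is
#'   discarded.
#' @param pixel_size voxel size in Angstrom (used for nm conversions; when
#'   `NULL` the prediction volume's own voxel size is used).
#' @return A list of class `pick_config`.
#' @export
pick_config <- function(threshold = 0.5, min_volume_nm3 = 0,
                        min_spacing_nm = 0, pixel_size = NULL) {
  if (threshold <= 0 || threshold > 1) {
    stop_fmt("threshold must be in (0, 1]")
  }
  if (min_volume_nm3 < 0 || min_spacing_nm < 0) {
    stop_fmt("minimum volume and spacing must be >= 0")
  }
  structure(list(threshold = threshold, min_volume_nm3 = min_volume_nm3,
                 min_spacing_nm = min_spacing_nm, pixel_size = pixel_size),
            class = "pick_config")
}

cfg_pixel_size <- function(cfg, pred) cfg$pixel_size %||% pred$voxel_size

#' Partition a thresholded segmentation into particle groups
#'
#' Steps: (1) binarize at `cfg$threshold`; (2) 3D Euclidean distance
#' transform of the foreground (distance to the nearest zero voxel);
#' (3) watershed of the negated distance transform seeded at its local
#' maxima (26-connected; an equal-valued plateau contributes one seed, its
#' minimum voxel index). Every foreground voxel lands in exactly one group.
#'
#' @param pred a prediction [volume3d()] with values in `[0, 1]`.
#' @param cfg a [pick_config()].
#' @return A tibble of class `particle_groups` with one row per group
#'   (`group`, `n_voxels`, `weight` = sum of prediction values, and the
#'   unweighted centroid `cx`, `cy`, `cz` in 0-based voxel coordinates);
#'   the full label volume is attached as attribute `labels`.
#' @export
group_segmentation <- function(pred, cfg) {
  stopifnot(is_volume3d(pred), inherits(cfg, "pick_config"))
  check_prediction_volume(pred)
  d <- dim(pred$data)
  fg <- pred$data >= cfg$threshold
  if (!any(fg)) {
    out <- tibble::tibble(group = integer(), n_voxels = integer(),
                          weight = numeric(), cx = numeric(), cy = numeric(),
                          cz = numeric())
    attr(out, "labels") <- array(0L, d)
    attr(out, "pixel_size") <- cfg_pixel_size(cfg, pred)
    class(out) <- c("particle_groups", class(out))
    return(out)
  }
  # squared distance of each foreground voxel to the nearest background voxel
  d2 <- cpp_edt_sq(!fg, d, slicewise = FALSE)
  seeds <- cpp_plateau_maxima(d2, fg, d)
  labels <- cpp_watershed(d2, fg, seeds, d)
  k <- length(seeds)
  idx <- which(labels > 0)
  lab <- labels[idx]
  n_vox <- tabulate(lab, nbins = k)
  wsum <- as.vector(rowsum(pred$data[idx], lab, reorder = TRUE))
  co <- arrayInd(idx, d) - 1L  # 0-based voxel coordinates
  cx <- as.vector(rowsum(as.numeric(co[, 1]), lab)) / n_vox
  cy <- as.vector(rowsum(as.numeric(co[, 2]), lab)) / n_vox
  cz <- as.vector(rowsum(as.numeric(co[, 3]), lab)) / n_vox
  out <- tibble::tibble(group = seq_len(k), n_voxels = n_vox, weight = wsum,
                        cx = cx, cy = cy, cz = cz)
  attr(out, "labels") <- labels
  attr(out, "pixel_size") <- cfg_pixel_size(cfg, pred)
  class(out) <- c("particle_groups", class(out))
  out
}

#' Discard groups below the minimum particle volume
#'
#' A group of `n` voxels has physical volume `n * (pixel_size / 10)^3` nm^3;
#' groups below `cfg$min_volume_nm3` are removed ("dust").
#'
#' @param groups a `particle_groups` tibble from [group_segmentation()].
#' @param cfg a [pick_config()].
#' @return The filtered `particle_groups` tibble.
#' @export
filter_min_volume <- function(groups, cfg) {
  px <- attr(groups, "pixel_size") %||% cfg$pixel_size %||% 10
  keep <- voxels_to_nm3(groups$n_voxels, px) >= cfg$min_volume_nm3
  subset_groups(groups, keep)
}

#' Suppress groups closer than the minimum particle spacing
#'
#' Groups are visited in descending weight (ties broken by ascending
#' centroid, lexicographically); a group is retained iff its centroid lies at
#' least `min_spacing_nm` from every already-retained centroid.
#'
#' @inheritParams filter_min_volume
#' @return The filtered `particle_groups` tibble.
#' @export
suppress_close_groups <- function(groups, cfg) {
  if (cfg$min_spacing_nm <= 0 || nrow(groups) < 2) return(groups)
  px <- attr(groups, "pixel_size") %||% cfg$pixel_size %||% 10
  min_px <- nm_to_px(cfg$min_spacing_nm, px)
  ord <- order(-groups$weight, groups$cx, groups$cy, groups$cz)
  kept <- integer()
  cen <- cbind(groups$cx, groups$cy, groups$cz)
  for (i in ord) {
    if (!length(kept)) {
      kept <- i
      next
    }
    dd <- sqrt(colSums((t(cen[kept, , drop = FALSE]) - cen[i, ])^2))
    if (all(dd >= min_px)) kept <- c(kept, i)
  }
  keep <- rep(FALSE, nrow(groups))
  keep[kept] <- TRUE
  subset_groups(groups, keep)
}

subset_groups <- function(groups, keep) {
  out <- groups[keep, , drop = FALSE]
  attr(out, "labels") <- attr(groups, "labels")
  attr(out, "pixel_size") <- attr(groups, "pixel_size")
  class(out) <- class(groups)
  out
}

#' Pick particles from a segmented volume
#'
#' Composes the full picking procedure: [group_segmentation()], weight
#' computation, [filter_min_volume()], [suppress_close_groups()], then each
#' retained group's unweighted voxel centroid is rounded half-up to integer
#' voxel coordinates. Particles are sorted by descending weight.
#'
#' @param pred a prediction [volume3d()].
#' @param cfg a [pick_config()].
#' @param feature_name feature name recorded on the particle set.
#' @param source_volume optional path recorded on the particle set.
#' @return A [particle_set()] tibble (`x`, `y`, `z`, `weight`).
#' @export
pick_particles <- function(pred, cfg, feature_name = "feature",
                           source_volume = NA_character_) {
  groups <- group_segmentation(pred, cfg)
  groups <- filter_min_volume(groups, cfg)
  groups <- suppress_close_groups(groups, cfg)
  ord <- order(-groups$weight, groups$cx, groups$cy, groups$cz)
  g <- groups[ord, , drop = FALSE]
  particle_set(round_half_up(g$cx), round_half_up(g$cy), round_half_up(g$cz),
               weight = g$weight, feature_name = feature_name,
               source_volume = source_volume, bounds = dim(pred$data))
}
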