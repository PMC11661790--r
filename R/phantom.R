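# Synthetic tomogram-like phantoms with per-feature ground truth.
#
# The scene emulates the contents of a typical cryoET field of view at the
# scale the package targets: vesicle membranes (spherical shells, ~5 nm
# thick), an optional carbon-film-like slab with a straight edge, small
# disc-shaped platforms held at a fixed offset outside membrane surfaces
# (membrane-bound particle analogue; default 22 nm), solid-sphere granules
# and cylindrical filaments, plus additive Gaussian noise. Feature voxels are
# dense (high values) on a low background; `invert = TRUE` flips the
# contrast to the opposite display convention.

#' Phantom configuration
#'
#' @param shape volume shape as `c(nz, ny, nx)` voxels.
#' @param pixel_size voxel size in Angstrom.
#' @param n_vesicles number of membrane vesicles (spherical shells).
#' @param vesicle_radius_range_nm min/max vesicle radius in nm.
#' @param membrane_thickness_nm shell thickness in nm.
#' @param n_platforms number of membrane-bound platforms, placed at
#'   `platform_offset_nm` outside vesicle membrane surfaces with in-plane
#'   (xy) direction vectors.
#' @param platform_offset_nm distance from the membrane surface to the
#'   platform centre, in nm.
#' @param platform_radius_nm,platform_thickness_nm platform disc dimensions.
#' @param carbon_slab add a carbon-film-like slab covering `x >= edge`.
#' @param n_granules number of solid-sphere granules.
#' @param granule_radius_range_nm min/max granule radius in nm.
#' @param n_filaments number of cylindrical filaments.
#' @param filament_radius_nm filament radius in nm.
#' @param noise_sigma standard deviation of the additive Gaussian noise,
#'   relative to the feature/background contrast of 1.
#' @param object_bounds optional fractional placement bounds
#'   `c(x0, x1, y0, y1, z0, z1)` in `[0, 1]` restricting where objects are
#'   placed (e.g. to leave part of the field of view empty, as real
#'   tomograms often do).
#' @param invert flip the contrast convention (features dark).
#' @param z_blur_sigma optional Gaussian blur (in voxels) along z only,
#'   roughly emulating anisotropic resolution; 0 disables it.
#' @param seed integer RNG seed; the phantom is reproducible from it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(48, 128, 128), pixel_size = 10,
                           n_vesicles = 3,
                           vesicle_radius_range_nm = c(10, 16),
                           membrane_thickness_nm = 5,
                           n_platforms = 0, platform_offset_nm = 22,
                           platform_radius_nm = 6, platform_thickness_nm = 5,
                           carbon_slab = FALSE,
                           n_granules = 0, granule_radius_range_nm = c(6, 9),
                           n_filaments = 0, filament_radius_nm = 3,
                           noise_sigma = 0.3, object_bounds = NULL,
                           invert = FALSE, z_blur_sigma = 0, seed = 1) {
  counts <- c(n_vesicles, n_platforms, n_granules, n_filaments)
  if (any(counts < 0)) stop_fmt("all object counts must be >= 0")
  if (n_platforms > 0 && n_vesicles == 0) {
    stop_fmt("platforms require at least one vesicle to bind to")
  }
  structure(as.list(environment()), class = "phantom_config")
}

# linear indices of voxels with rlo^2 <= |p - center|^2 <= rhi^2, computed on
# the bounding sub-box only; center in 0-based voxel coordinates
sphere_indices <- function(d, center, rlo, rhi) {
  rng <- lapply(1:3, function(k) {
    max(1L, floor(center[k] - rhi) + 1L):min(d[k], ceiling(center[k] + rhi) + 1L)
  })
  dx2 <- (rng[[1]] - 1 - center[1])^2
  dy2 <- (rng[[2]] - 1 - center[2])^2
  dz2 <- (rng[[3]] - 1 - center[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  sel <- which(r2 >= rlo^2 & r2 <= rhi^2)
  if (!length(sel)) return(integer())
  co <- arrayInd(sel, dim(r2))
  (rng[[3]][co[, 3]] - 1) * d[1] * d[2] + (rng[[2]][co[, 2]] - 1) * d[1] +
    rng[[1]][co[, 1]]
}

# disc of radius r and half-thickness h centred at `center`, axis `u`
disc_indices <- function(d, center, u, r, h) {
  ext <- sqrt(r^2 + h^2) + 1
  rng <- lapply(1:3, function(k) {
    max(1L, floor(center[k] - ext) + 1L):min(d[k], ceiling(center[k] + ext) + 1L)
  })
  g <- expand.grid(x = rng[[1]] - 1, y = rng[[2]] - 1, z = rng[[3]] - 1)
  v <- cbind(g$x - center[1], g$y - center[2], g$z - center[3])
  a <- v %*% u
  perp2 <- rowSums(v^2) - a^2
  sel <- which(abs(a) <= h & perp2 <= r^2)
  if (!length(sel)) return(integer())
  g$z[sel] * d[1] * d[2] + g$y[sel] * d[1] + g$x[sel] + 1
}

# distance from points (rows of P) to the infinite line through q with
# direction u (unit)
line_distance <- function(P, q, u) {
  v <- sweep(P, 2, q)
  a <- as.vector(v %*% u)
  sqrt(pmax(rowSums(v^2) - a^2, 0))
}

placement_bounds_px <- function(cfg, d) {
  b <- cfg$object_bounds %||% c(0, 1, 0, 1, 0, 1)
  list(lo = c(b[1] * (d[1] - 1), b[3] * (d[2] - 1), b[5] * (d[3] - 1)),
       hi = c(b[2] * (d[1] - 1), b[4] * (d[2] - 1), b[6] * (d[3] - 1)))
}

#' Generate a phantom tomogram with ground truth
#'
#' Objects are placed by rejection sampling without overlap (bounded
#' retries); the density volume is the union of all feature masks at
#' contrast 1 over a 0 background, plus Gaussian noise. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return A list: `volume` (noisy [volume3d()]), `ground_truth` (named list
#'   of binary [volume3d()]s, one per feature present), and `cfg`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- rev(cfg$shape) # (nx, ny, nz)
  px <- cfg$pixel_size
  nm <- function(v) nm_to_px(v, px)
  bounds <- placement_bounds_px(cfg, d)
  gt <- list()
  add_gt <- function(feature, idx) {
    if (is.null(gt[[feature]])) gt[[feature]] <<- array(0, d)
    gt[[feature]][idx] <<- 1
  }

  with_seed(cfg$seed, {
    placed <- list() # spheres of influence: list(center, radius)
    # the carbon film occupies x >= edge_x (0-based); objects stay clear
    edge_x <- if (isTRUE(cfg$carbon_slab)) floor(0.72 * d[1]) else d[1] + 2
    # margin: per-axis distance the object (plus any attachments) needs from
    # the volume faces; sep: radius used for object-object separation
    place_sphere <- function(margin, sep, what, tries = 400) {
      margin <- rep_len(margin, 3)
      for (i in seq_len(tries)) {
        c0 <- sapply(1:3, function(k) {
          lo <- max(bounds$lo[k], margin[k])
          hi <- min(bounds$hi[k], d[k] - 1 - margin[k])
          if (k == 1) hi <- min(hi, edge_x - 2 - margin[k])
          if (hi < lo) return(NA_real_)
          runif(1, lo, hi)
        })
        if (anyNA(c0)) {
          stop_fmt("%s with margin %.1f px does not fit the volume/bounds",
                   what, max(margin))
        }
        ok <- all(vapply(placed, function(p) {
          sqrt(sum((p$center - c0)^2)) >= p$radius + sep + 2
        }, logical(1)))
        if (ok) {
          placed[[length(placed) + 1]] <<- list(center = c0, radius = sep)
          return(c0)
        }
      }
      stop_fmt("could not place %s without overlap after %d retries",
               what, tries)
    }

    thick <- nm(cfg$membrane_thickness_nm)
    # platforms attach in-plane, so only the xy bounds margin must reserve
    # room for them
    plat_zone <- if (cfg$n_platforms > 0) {
      nm(cfg$platform_offset_nm) + nm(cfg$platform_radius_nm) + 1
    } else 0

    vesicles <- list()
    for (i in seq_len(cfg$n_vesicles)) {
      r <- nm(runif(1, cfg$vesicle_radius_range_nm[1],
                    cfg$vesicle_radius_range_nm[2]))
      c0 <- place_sphere(c(r + thick / 2 + plat_zone,
                           r + thick / 2 + plat_zone,
                           r + thick / 2),
                         sep = r + thick / 2, what = "vesicle")
      vesicles[[i]] <- list(center = c0, radius = r)
      add_gt("membrane", sphere_indices(d, c0, r - thick / 2, r + thick / 2))
    }

    if (cfg$n_platforms > 0) {
      host <- rep_len(seq_along(vesicles), cfg$n_platforms)
      plat_centers <- matrix(numeric(), 0, 3)
      rp <- nm(cfg$platform_radius_nm)
      hp <- nm(cfg$platform_thickness_nm) / 2
      for (i in seq_len(cfg$n_platforms)) {
        ves <- vesicles[[host[i]]]
        dist_c <- ves$radius + thick / 2 + nm(cfg$platform_offset_nm)
        done <- FALSE
        for (try in 1:400) {
          th <- runif(1, 0, 2 * pi)
          u <- c(cos(th), sin(th), 0)
          c0 <- ves$center + dist_c * u
          if (any(c0 < rp + 1) || any(c0 > d - rp - 2) ||
              c0[1] > edge_x - 2 - rp) next
          if (nrow(plat_centers) &&
              min(sqrt(rowSums(sweep(plat_centers, 2, c0)^2))) <
                2 * rp + 2) next
          # keep clear of every other vesicle's membrane
          clear <- all(vapply(vesicles[-host[i]], function(v2) {
            sqrt(sum((v2$center - c0)^2)) > v2$radius + thick / 2 + rp + 2
          }, logical(1)))
          if (!clear) next
          plat_centers <- rbind(plat_centers, c0)
          placed[[length(placed) + 1]] <- list(center = c0, radius = rp)
          add_gt("platform", disc_indices(d, c0, u, rp, hp))
          done <- TRUE
          break
        }
        if (!done) {
          stop_fmt("could not place platform %d on vesicle %d without overlap",
                   i, host[i])
        }
      }
    }

    for (i in seq_len(cfg$n_granules)) {
      r <- nm(runif(1, cfg$granule_radius_range_nm[1],
                    cfg$granule_radius_range_nm[2]))
      c0 <- place_sphere(r + 1, sep = r, what = "granule")
      add_gt("granule", sphere_indices(d, c0, 0, r))
    }

    if (cfg$n_filaments > 0) {
      rf <- nm(cfg$filament_radius_nm)
      co_all <- NULL
      for (i in seq_len(cfg$n_filaments)) {
        done <- FALSE
        for (try in 1:400) {
          q <- sapply(1:3, function(k) runif(1, bounds$lo[k], bounds$hi[k]))
          th <- runif(1, 0, 2 * pi)
          phi <- runif(1, -0.3, 0.3) # mostly in-plane, like real filaments
          u <- c(cos(th) * cos(phi), sin(th) * cos(phi), sin(phi))
          ok <- all(vapply(placed, function(p) {
            a <- sum((p$center - q) * u)
            sqrt(max(sum((p$center - q)^2) - a^2, 0)) >= p$radius + rf + 2
          }, logical(1)))
          if (!ok) next
          if (is.null(co_all)) {
            co_all <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                            z = 0:(d[3] - 1)))
          }
          idx <- which(line_distance(co_all, q, u) <= rf &
                         co_all[, 1] <= edge_x - 2)
          if (length(idx) < 10) next
          add_gt("filament", idx)
          done <- TRUE
          break
        }
        if (!done) stop_fmt("could not place filament %d without overlap", i)
      }
    }

    if (isTRUE(cfg$carbon_slab)) {
      zc <- d[3] / 2
      hz <- max(nm(15) / 2, 1.5)
      arr <- array(0, d)
      zs <- which(abs((1:d[3]) - 1 - zc) <= hz)
      arr[(edge_x + 1):d[1], , zs] <- 1
      add_gt("carbon", which(arr > 0))
    }

    density <- array(0, d)
    for (f in names(gt)) density[gt[[f]] > 0] <- 1
    if (cfg$z_blur_sigma > 0) {
      density <- blur_z(density, cfg$z_blur_sigma)
    }
    if (cfg$noise_sigma > 0) {
      density <- density + array(rnorm(length(density), 0, cfg$noise_sigma), d)
    }
    if (isTRUE(cfg$invert)) density <- -density
  })

  list(volume = volume3d(density, voxel_size = px),
       ground_truth = lapply(gt, volume3d, voxel_size = px),
       cfg = cfg)
}

# Gaussian blur along z only (separable 1D convolution, reflected edges).
blur_z <- function(arr, sigma) {
  d <- dim(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  idx <- outer(seq_len(d[3]), -half:half, `+`)
  idx[idx < 1] <- 2 - idx[idx < 1]
  idx[idx > d[3]] <- 2 * d[3] - idx[idx > d[3]]
  out <- matrix(0, d[1] * d[2], d[3])
  for (j in seq_along(k)) out <- out + k[j] * m[, idx[, j]]
  array(out, d)
}

#' Sample annotation boxes from a phantom
#'
#' Positive boxes are centred on random foreground voxels of the feature's
#' ground truth, with the cropped ground-truth slice as label mask; negative
#' boxes are centred on voxels at least `clearance_px` (one box width by
#' default) from any foreground voxel of that feature, with all-zero labels.
#'
#' @param phantom output of [generate_phantom()].
#' @param feature feature name present in the phantom's ground truth.
#' @param n_pos,n_neg numbers of positive / negative boxes.
#' @param seed integer RNG seed.
#' @param box_size box edge in pixels.
#' @param clearance_px minimum 3D distance (voxels) from a negative box
#'   centre to the feature's foreground.
#' @return An [annotation_boxes()] table.
#' @export
generate_training_boxes <- function(phantom, feature, n_pos, n_neg, seed = 1,
                                    box_size = 64, clearance_px = box_size) {
  gtv <- phantom$ground_truth[[feature]]
  if (is.null(gtv)) {
    stop_fmt("feature '%s' is not present in the phantom (features: %s)",
             feature, paste(names(phantom$ground_truth), collapse = ", "))
  }
  gt <- gtv$data
  d <- dim(gt)
  pos_pool <- which(gt > 0)
  if (length(pos_pool) < n_pos) {
    stop_fmt("only %d positive centers available for '%s' (requested %d)",
             length(pos_pool), feature, n_pos)
  }
  d2 <- cpp_edt_sq(gt > 0, d, slicewise = FALSE)
  # negatives must keep their clearance after extraction, so only accept
  # centres whose box fits without edge-clamping
  half <- box_size %/% 2
  co_all <- arrayInd(which(d2 >= clearance_px^2), d) - 1L
  ok <- co_all[, 1] >= half & co_all[, 1] <= d[1] - box_size + half &
    co_all[, 2] >= half & co_all[, 2] <= d[2] - box_size + half
  co_all <- co_all[ok, , drop = FALSE]
  neg_pool <- co_all[, 1] + 1L + co_all[, 2] * d[1] +
    co_all[, 3] * d[1] * d[2]
  if (length(neg_pool) < n_neg) {
    stop_fmt("only %d negative centers at clearance %d px (requested %d)",
             length(neg_pool), clearance_px, n_neg)
  }
  with_seed(seed, {
    pos_idx <- sample(pos_pool, n_pos)
    neg_idx <- sample(neg_pool, n_neg)
  })
  co <- arrayInd(c(pos_idx, neg_idx), d) - 1L
  positive <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  half <- box_size %/% 2
  masks <- vector("list", n_pos + n_neg)
  xs <- ys <- integer(n_pos + n_neg)
  for (i in seq_len(n_pos + n_neg)) {
    cx <- clamp_center(co[i, 1], box_size, d[1])
    cy <- clamp_center(co[i, 2], box_size, d[2])
    xs[i] <- cx; ys[i] <- cy
    if (positive[i]) {
      masks[[i]] <- gt[(cx - half + 1):(cx + half),
                       (cy - half + 1):(cy + half), co[i, 3] + 1]
    }
  }
  annotation_boxes("phantom", co[, 3], xs, ys, positive, masks)
}
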