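# Independent oracles and fixture builders used across tests. These
# deliberately avoid the package's C++ routines: components by min-label
# propagation, dilation by exhaustive per-voxel distance checks.

# 26-connected component labelling by brute-force min-label propagation.
# Returns an integer volume, 0 = background, components numbered by first
# (raster-order) voxel.
oracle_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(array(0L, d))
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nb <- lapply(seq_len(nrow(offs)), function(k) {
    nc <- sweep(co, 2, offs[k, ], `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] & nc[, 2] >= 1 & nc[, 2] <= d[2] &
      nc[, 3] >= 1 & nc[, 3] <= d[3]
    v <- rep(NA_integer_, length(idx))
    lin <- nc[ok, 1] + (nc[ok, 2] - 1) * d[1] + (nc[ok, 3] - 1) * d[1] * d[2]
    p <- pos[lin]
    v[ok][p > 0] <- p[p > 0]
    v
  })
  lab <- seq_along(idx)
  repeat {
    new <- lab
    for (k in seq_along(nb)) {
      v <- nb[[k]]
      ok <- !is.na(v)
      new[ok] <- pmin(new[ok], new[v[ok]])
    }
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, d)
  out[idx] <- match(lab, unique(lab))
  out
}

# Canonical renumbering of a label volume so two labelings can be compared
# as partitions.
canonical_labels <- function(lab) {
  v <- lab[lab > 0]
  lab[lab > 0] <- match(v, unique(v))
  lab
}

# Per-slice disk dilation by exhaustive distance check: voxel included iff
# its in-plane Euclidean distance to some thresholded parent voxel in the
# same slice is <= radius_px.
oracle_dilate_slicewise <- function(parent, threshold, radius_px) {
  d <- dim(parent)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    sl <- parent[, , z] >= threshold
    pts <- which(sl, arr.ind = TRUE)
    if (!nrow(pts)) next
    gx <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
    gy <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
    mind2 <- array(Inf, c(d[1], d[2]))
    for (i in seq_len(nrow(pts))) {
      mind2 <- pmin(mind2, (gx - pts[i, 1])^2 + (gy - pts[i, 2])^2)
    }
    out[, , z] <- mind2 <= radius_px^2 + 1e-9
  }
  out
}

# Solid sphere indicator on a grid (0-based center coordinates).
sphere_voxels <- function(d, center, radius) {
  x <- (seq_len(d[1]) - 1 - center[1])^2
  y <- (seq_len(d[2]) - 1 - center[2])^2
  z <- (seq_len(d[3]) - 1 - center[3])^2
  array(outer(outer(x, y, `+`), z, `+`) <= radius^2, d)
}

# Smoothly sampled sphere field (2-voxel linear ramp at the boundary), the
# band-limited construction appropriate for isosurface extraction.
sphere_field <- function(d, center, radius) {
  x <- (seq_len(d[1]) - 1 - center[1])^2
  y <- (seq_len(d[2]) - 1 - center[2])^2
  z <- (seq_len(d[3]) - 1 - center[3])^2
  r <- sqrt(array(outer(outer(x, y, `+`), z, `+`), d))
  pmin(pmax((radius + 1 - r) / 2, 0), 1)
}

# Random volume of well-separated solid spheres (each component has a unique
# distance-transform maximum plateau). Returns list(vol, n_spheres).
random_sphere_volume <- function(d = c(32, 32, 32), max_spheres = 4) {
  n_target <- sample.int(max_spheres, 1)
  centers <- matrix(numeric(), 0, 3)
  radii <- numeric()
  for (i in seq_len(n_target * 20)) {
    if (length(radii) >= n_target) break
    r <- runif(1, 2, 5)
    c0 <- sapply(d, function(n) runif(1, r + 1, n - r - 2))
    if (nrow(centers) &&
        min(sqrt(rowSums(sweep(centers, 2, c0)^2)) - radii) < r + 3) next
    centers <- rbind(centers, c0)
    radii <- c(radii, r)
  }
  arr <- array(0, d)
  for (i in seq_along(radii)) {
    arr[sphere_voxels(d, centers[i, ], radii[i])] <- 1
  }
  list(vol = tomoseg::volume3d(arr, voxel_size = 10), n_spheres = length(radii))
}

mesh_area <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  cc <- m$vertices[m$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# Number of connected surface components (faces sharing a vertex connect).
mesh_component_count <- function(m) {
  if (!nrow(m$faces)) return(0L)
  parent <- seq_len(nrow(m$vertices))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(m$faces))) {
    a <- find(m$faces[r, 1])
    for (k in 2:3) {
      b <- find(m$faces[r, k])
      if (a != b) parent[b] <- a
    }
  }
  length(unique(vapply(unique(as.vector(m$faces)), find, integer(1))))
}

# An independent, minimal OBJ parser (token level, no package code).
oracle_parse_obj <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "\\s+")
  v <- do.call(rbind, lapply(toks[vapply(toks, function(t) t[1] == "v",
                                         logical(1))],
                             function(t) as.numeric(t[2:4])))
  f <- do.call(rbind, lapply(toks[vapply(toks, function(t) t[1] == "f",
                                         logical(1))],
                             function(t) as.integer(t[2:4])))
  list(vertices = v %||% matrix(numeric(), 0, 3),
       faces = f %||% matrix(integer(), 0, 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic annotation samples table (the shape extract_boxes() returns)
# with known content, for training-set arithmetic tests.
make_samples <- function(n_pos, n_neg, box = 64, seed = 1) {
  set.seed(seed)
  mk <- function(positive) {
    img <- matrix(rnorm(box * box), box, box)
    lab <- matrix(0, box, box)
    if (positive) lab[sample(box^2, 25)] <- 1
    list(image = img, label = lab)
  }
  pos <- replicate(n_pos, mk(TRUE), simplify = FALSE)
  neg <- replicate(n_neg, mk(FALSE), simplify = FALSE)
  all <- c(pos, neg)
  tibble::tibble(image = lapply(all, `[[`, "image"),
                 label = lapply(all, `[[`, "label"),
                 positive = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}
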