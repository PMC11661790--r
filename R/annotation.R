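# Sparse box annotations and their conversion into balanced training sets.

#' Build a table of annotation boxes
#'
#' Each row is one annotated box on one tomographic slice: a feature is either
#' present (`positive`, with a binary label mask) or absent (`negative`,
#' all-zero labels). Coordinates are 0-based voxel indices; `z` is the slice.
#'
#' @param dataset_id text id of the source volume.
#' @param z integer slice indices.
#' @param x,y integer box-center coordinates within the slice.
#' @param positive logical; whether the box contains the feature.
#' @param label_mask list of binary `box_size x box_size` matrices; may be
#'   `NULL` entries for negative boxes (treated as all-zero).
#' @return A tibble of class `annotation_boxes`.
#' @export
annotation_boxes <- function(dataset_id, z, x, y, positive,
                             label_mask = vector("list", length(z))) {
  n <- length(z)
  stopifnot(length(x) == n, length(y) == n, length(positive) == n,
            length(label_mask) == n)
  for (i in seq_len(n)) {
    m <- label_mask[[i]]
    if (positive[i]) {
      if (is.null(m) || sum(m != 0) < 1) {
        stop_fmt("positive box %d must have >= 1 nonzero label pixel", i)
      }
    } else if (!is.null(m) && any(m != 0)) {
      stop_fmt("negative box %d must have an all-zero label mask", i)
    }
  }
  out <- tibble::tibble(dataset_id = rep_len(as.character(dataset_id), n),
                        z = as.integer(z), x = as.integer(x),
                        y = as.integer(y), positive = as.logical(positive),
                        label_mask = label_mask)
  class(out) <- c("annotation_boxes", class(out))
  out
}

# Clamp a 0-based box center so a box_size crop fits inside [0, n).
clamp_center <- function(c0, box_size, n) {
  half <- box_size %/% 2
  min(max(c0, half), n - box_size + half)
}

#' Extract normalized image/label patches for annotation boxes
#'
#' Crops a `box_size` square around each box center from the stated slice.
#' Centers too close to an edge are shifted inward so the box fits (a message
#' reports each shift; boxes are never dropped). Images are normalized per
#' patch to zero mean and unit variance (flat patches map to zeros); label
#' masks are passed through unchanged.
#'
#' @param volume a [volume3d()].
#' @param boxes an [annotation_boxes()] table.
#' @param box_size patch edge length in pixels; must be even.
#' @return A tibble with list-columns `image` and `label` plus `positive`.
#' @export
extract_boxes <- function(volume, boxes, box_size = 64) {
  stopifnot(is_volume3d(volume))
  if (box_size %% 2 != 0) stop_fmt("`box_size` must be even")
  d <- dim(volume$data)
  if (any(boxes$z < 0 | boxes$z >= d[3])) {
    stop_fmt("box slice_index outside volume (0..%d)", d[3] - 1)
  }
  half <- box_size %/% 2
  n <- nrow(boxes)
  images <- labels <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- clamp_center(boxes$x[i], box_size, d[1])
    cy <- clamp_center(boxes$y[i], box_size, d[2])
    if (cx != boxes$x[i] || cy != boxes$y[i]) {
      message(sprintf("box %d center (%d, %d) shifted to (%d, %d) to fit",
                      i, boxes$x[i], boxes$y[i], cx, cy))
    }
    xs <- (cx - half + 1):(cx + half)   # 1-based array indices
    ys <- (cy - half + 1):(cy + half)
    patch <- volume$data[xs, ys, boxes$z[i] + 1]
    images[[i]] <- normalize_patch(patch)
    m <- boxes$label_mask[[i]]
    if (is.null(m)) m <- matrix(0, box_size, box_size)
    if (!all(dim(m) == box_size)) {
      stop_fmt("label mask %d is %s, expected %d x %d", i,
               paste(dim(m), collapse = "x"), box_size, box_size)
    }
    labels[[i]] <- (m != 0) * 1
  }
  tibble::tibble(image = images, label = labels, positive = boxes$positive)
}

# The 8 dihedral (square-symmetry) transforms; k in 0..7.
# k %% 4 quarter-turns, k >= 4 adds a flip. Exact for binary labels.
dihedral_transform <- function(m, k) {
  if (k >= 4) m <- m[nrow(m):1, , drop = FALSE]
  for (i in seq_len(k %% 4)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Resample annotated patches into a balanced, augmented training set
#'
#' Every positive patch is emitted `copies` times; negatives are drawn
#' uniformly with replacement from the negative pool until the emitted
#' negative:positive ratio is `neg_ratio` (count rounded half-up). Every
#' emitted patch receives a random orientation, one of the 8 dihedral
#' transforms (4 rotations x optional flip), applied identically to image and
#' label, and the output order is shuffled. Fully reproducible from `seed`.
#'
#' @param samples patch table from [extract_boxes()].
#' @param copies emitted copies per positive patch.
#' @param neg_ratio target ratio of emitted negatives to emitted positives.
#' @param seed integer RNG seed.
#' @param feature_name feature the set trains for.
#' @param pixel_size pixel size in Angstrom of the source data.
#' @return A `training_set`: list with `images` and `labels` arrays of dim
#'   `c(box_size, box_size, n)`, `counts = c(n_positive, n_negative)`,
#'   `feature_name`, `box_size`, `pixel_size`.
#' @export
resample_training_set <- function(samples, copies = 10, neg_ratio = 1.3,
                                  seed = 1, feature_name = "feature",
                                  pixel_size = 10) {
  pos <- which(samples$positive)
  neg <- which(!samples$positive)
  if (!length(pos)) stop_fmt("training set needs >= 1 positive sample")
  n_pos_out <- copies * length(pos)
  n_neg_out <- round_half_up(neg_ratio * n_pos_out)
  if (!length(neg) && n_neg_out > 0) {
    warn_fmt("no negative samples available; emitting 0 negatives")
    n_neg_out <- 0
  }
  box_size <- nrow(samples$image[[1]])
  with_seed(seed, {
    src <- c(rep(pos, each = copies),
             if (n_neg_out) neg[sample.int(length(neg), n_neg_out,
                                           replace = TRUE)])
    orient <- sample(0:7, length(src), replace = TRUE)
    ord <- sample.int(length(src))
  })
  src <- src[ord]
  orient <- orient[ord]
  n <- length(src)
  images <- array(0, c(box_size, box_size, n))
  labels <- array(0, c(box_size, box_size, n))
  for (i in seq_len(n)) {
    images[, , i] <- dihedral_transform(samples$image[[src[i]]], orient[i])
    labels[, , i] <- dihedral_transform(samples$label[[src[i]]], orient[i])
  }
  structure(list(feature_name = feature_name, box_size = box_size,
                 images = images, labels = labels, pixel_size = pixel_size,
                 counts = c(n_positive = n_pos_out, n_negative = n_neg_out)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> '%s': %d patches (%d pos, %d neg), %dx%d px @ %.3g A/px\n",
              x$feature_name, dim(x$images)[3], x$counts[1], x$counts[2],
              x$box_size, x$box_size, x$pixel_size))
  invisible(x)
}

#' Write / read an annotation manifest
#'
#' Boxes are serialized as a tab-separated manifest (`dataset_id`, `z`, `x`,
#' `y`, `positive`, `mask` file name) with each positive box's label mask
#' stored as a one-slice MRC raster next to it.
#'
#' @param boxes an [annotation_boxes()] table.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_annotation_manifest <- function(boxes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_files <- character(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    m <- boxes$label_mask[[i]]
    if (!is.null(m) && any(m != 0)) {
      mask_files[i] <- sprintf("mask_%04d.mrc", i)
      write_mrc(volume3d(array((m != 0) * 1, c(dim(m), 1)), voxel_size = 1),
                file.path(dir, mask_files[i]))
    } else {
      mask_files[i] <- "-"
    }
  }
  df <- data.frame(dataset_id = boxes$dataset_id, z = boxes$z, x = boxes$x,
                   y = boxes$y, positive = as.integer(boxes$positive),
                   mask = mask_files)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_manifest
#' @export
read_annotation_manifest <- function(dir) {
  path <- file.path(dir, "manifest.tsv")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  masks <- lapply(df$mask, function(f) {
    if (identical(f, "-")) NULL
    else read_mrc(file.path(dir, f))$data[, , 1]
  })
  annotation_boxes(df$dataset_id, df$z, df$x, df$y, df$positive == 1, masks)
}
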