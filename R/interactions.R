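# Model interactions (colocalization / avoidance) and model competition.
#
# Both are suppression-only edits of prediction volumes: output values never
# exceed the input. Interactions act per z-slice with a circular (disk)
# kernel, matching slice-wise segmentation; a 3D spherical kernel is
# available behind `kernel_3d`.

#' Specify a model interaction
#'
#' The parent's predictions are thresholded into a binary mask which is then
#' dilated by a disk of interaction radius `radius_nm`; the child's
#' predictions are multiplied by the mask (`colocalize`) or by its complement
#' (`avoid`).
#'
#' @param parent_feature,child_feature feature names (must differ).
#' @param kind `"colocalize"` or `"avoid"`.
#' @param parent_threshold mask threshold in `[0, 1]`.
#' @param radius_nm interaction radius R in nanometres (>= 0).
#' @return A list of class `interaction_spec`.
#' @export
interaction_spec <- function(parent_feature, child_feature,
                             kind = c("colocalize", "avoid"),
                             parent_threshold = 0.5, radius_nm = 10) {
  kind <- match.arg(kind)
  if (identical(parent_feature, child_feature)) {
    stop_fmt("parent and child feature must differ")
  }
  if (parent_threshold < 0 || parent_threshold > 1) {
    stop_fmt("parent_threshold must be in [0, 1]")
  }
  if (radius_nm < 0) stop_fmt("radius_nm must be >= 0")
  structure(list(parent_feature = parent_feature,
                 child_feature = child_feature, kind = kind,
                 parent_threshold = parent_threshold, radius_nm = radius_nm),
            class = "interaction_spec")
}

#' Configure model competition
#'
#' @param emitting features whose predictions are entered into the
#'   competition.
#' @param absorbing features whose predictions can be suppressed. A feature
#'   may emit and absorb at the same time.
#' @return A list of class `competition_config`.
#' @export
competition_config <- function(emitting = character(),
                               absorbing = character()) {
  structure(list(emitting = as.character(emitting),
                 absorbing = as.character(absorbing)),
            class = "competition_config")
}

# Dilated parent mask: TRUE where the (2D in-slice, or 3D) Euclidean distance
# to the nearest thresholded parent voxel is <= radius_px. Exactly equals
# dilation by a disk/ball kernel of that radius.
dilated_mask <- function(parent_data, threshold, radius_px, kernel_3d) {
  mask <- parent_data >= threshold
  if (radius_px <= 0 || !any(mask)) {
    return(mask)
  }
  d2 <- cpp_edt_sq(mask, dim(parent_data), slicewise = !kernel_3d)
  array(d2 <= radius_px^2 + 1e-9, dim(parent_data))
}

#' Apply a colocalization or avoidance interaction
#'
#' Per z-slice, a binary mask is made by thresholding the parent prediction
#' volume at `spec$parent_threshold` and dilating it with a disk of radius
#' `round(radius_nm * 10 / pixel_size)` pixels. `colocalize` multiplies the
#' child by the mask, `avoid` by its complement. Output values never exceed
#' the input.
#'
#' @param child,parent prediction [volume3d()]s of identical shape.
#' @param spec an [interaction_spec()].
#' @param pixel_size pixel size in Angstrom used for the nm-to-px conversion
#'   (defaults to the child volume's voxel size).
#' @param kernel_3d use a 3D spherical kernel instead of the per-slice disk.
#' @param avoid_mode for `avoid` only: `"complement_after"` (default)
#'   suppresses everything within R of the thresholded parent —
#'   `child * (1 - dilate(mask))` — while `"complement_before"` keeps
#'   everything within R of the parent's complement,
#'   `child * dilate(1 - mask)`. The two differ in a band of width R around
#'   mask borders.
#' @return The edited child prediction volume.
#' @export
apply_interaction <- function(child, parent, spec, pixel_size = NULL,
                              kernel_3d = FALSE,
                              avoid_mode = c("complement_after",
                                             "complement_before")) {
  avoid_mode <- match.arg(avoid_mode)
  stopifnot(is_volume3d(child), is_volume3d(parent),
            inherits(spec, "interaction_spec"))
  if (!all(dim(child$data) == dim(parent$data))) {
    stop_fmt("child and parent volumes must have the same shape")
  }
  pixel_size <- pixel_size %||% child$voxel_size
  if (pixel_size <= 0) stop_fmt("pixel_size must be > 0")
  radius_px <- round_half_up(nm_to_px(spec$radius_nm, pixel_size))
  if (spec$radius_nm > 0 && radius_px == 0) {
    message(sprintf("interaction radius %.3g nm resolves to 0 px at %.3g A/px; no dilation",
                    spec$radius_nm, pixel_size))
  }
  edited <- if (spec$kind == "colocalize") {
    child$data * dilated_mask(parent$data, spec$parent_threshold, radius_px,
                              kernel_3d)
  } else if (avoid_mode == "complement_after") {
    child$data * !dilated_mask(parent$data, spec$parent_threshold, radius_px,
                               kernel_3d)
  } else {
    keep <- dilated_mask(1 - (parent$data >= spec$parent_threshold), 0.5,
                         radius_px, kernel_3d)
    child$data * keep
  }
  as_volume_like(array(edited, dim(child$data)), child)
}

#' Apply model competition
#'
#' For every voxel, each absorbing feature is set to zero wherever any other
#' emitting feature's prediction is strictly higher. All comparisons use the
#' original input values (simultaneous update), so the result does not depend
#' on feature order; ties preserve both values. Non-absorbing features pass
#' through unchanged.
#'
#' @param preds named list of prediction [volume3d()]s (same shape).
#' @param cfg a [competition_config()].
#' @return Named list of edited prediction volumes.
#' @export
apply_competition <- function(preds, cfg) {
  stopifnot(inherits(cfg, "competition_config"))
  feats <- names(preds)
  missing <- setdiff(c(cfg$emitting, cfg$absorbing), feats)
  if (length(missing)) {
    stop_fmt("competition references missing feature(s): %s",
             paste(missing, collapse = ", "))
  }
  if (!length(cfg$emitting)) {
    message("competition has an empty emitting set; identity")
    return(preds)
  }
  dims <- dim(preds[[1]]$data)
  for (f in feats) {
    if (!all(dim(preds[[f]]$data) == dims)) {
      stop_fmt("prediction volumes must all have the same shape")
    }
  }
  out <- preds
  for (f in intersect(cfg$absorbing, feats)) {
    rivals <- setdiff(cfg$emitting, f)
    if (!length(rivals)) next
    sup <- array(-Inf, dims)
    for (g in rivals) sup <- pmax(sup, preds[[g]]$data)
    edited <- preds[[f]]$data
    edited[sup > edited] <- 0
    out[[f]] <- as_volume_like(array(edited, dims), preds[[f]])
  }
  out
}

#' Apply a full interaction pipeline
#'
#' Competition is applied first (simultaneously, on the original
#' predictions), then the interactions in list order, each consuming the
#' current state — e.g. "membrane avoids carbon" followed by "platform
#' colocalizes with membrane" composes left to right.
#'
#' @param preds named list of prediction [volume3d()]s.
#' @param competition a [competition_config()] or `NULL`.
#' @param interactions list of [interaction_spec()]s, applied in order.
#' @param pixel_size pixel size in Angstrom (default: first volume's voxel
#'   size).
#' @param kernel_3d passed to [apply_interaction()].
#' @return Named list of edited prediction volumes.
#' @export
apply_pipeline <- function(preds, competition = NULL, interactions = list(),
                           pixel_size = NULL, kernel_3d = FALSE) {
  feats <- names(preds)
  for (sp in interactions) {
    bad <- setdiff(c(sp$parent_feature, sp$child_feature), feats)
    if (length(bad)) {
      stop_fmt("interaction references missing feature(s): %s",
               paste(bad, collapse = ", "))
    }
  }
  cur <- if (!is.null(competition)) apply_competition(preds, competition)
         else preds
  for (sp in interactions) {
    cur[[sp$child_feature]] <- apply_interaction(
      cur[[sp$child_feature]], cur[[sp$parent_feature]], sp,
      pixel_size = pixel_size, kernel_3d = kernel_3d)
  }
  cur
}
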