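# Training and slice-wise volume inference.

#' Training configuration
#'
#' Defaults follow common practice for small annotation sets: 50 epochs, 32
#' images per batch, and no validation split (all annotations are used for
#' training; with `validation_split > 0` the per-epoch reported losses are
#' validation losses instead of training losses).
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size images per gradient step (>= 1).
#' @param validation_split fraction in `[0, 1)` of patches held out.
#' @param seed integer seed for shuffling and the validation split.
#' @param learning_rate Adam learning rate.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, validation_split = 0,
                         seed = 1, learning_rate = 1e-3) {
  if (epochs < 1 || batch_size < 1) {
    stop_fmt("epochs and batch_size must be >= 1")
  }
  if (validation_split < 0 || validation_split >= 1) {
    stop_fmt("validation_split must be in [0, 1)")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_split = validation_split, seed = seed,
                 learning_rate = learning_rate),
            class = "train_config")
}

#' Train a segmentation model
#'
#' Minimizes pixel-wise binary cross-entropy with Adam. Reproducible: weight
#' initialization (via [build_model()]'s `seed`), shuffling and the
#' validation split are all driven by the given seeds.
#'
#' @param model an (untrained or trained) `seg_model`.
#' @param ts a `training_set` from [resample_training_set()].
#' @param cfg a [train_config()].
#' @return The trained model with `loss_history` filled (one value per
#'   epoch; validation losses when `validation_split > 0`).
#' @export
train_model <- function(model, ts, cfg = train_config()) {
  stopifnot(inherits(model, "seg_model"), inherits(ts, "training_set"))
  n <- dim(ts$images)[3]
  if (n < 1) stop_fmt("training set is empty")
  if (ts$box_size != model$box_size) {
    stop_fmt("training set box size %d != model box size %d",
             ts$box_size, model$box_size)
  }
  x_all <- array(ts$images, c(ts$box_size, ts$box_size, 1, n))
  y_all <- array(ts$labels, c(ts$box_size, ts$box_size, 1, n))

  idx <- seq_len(n)
  val_idx <- integer()
  if (cfg$validation_split > 0) {
    n_val <- max(1L, floor(cfg$validation_split * n))
    with_seed(cfg$seed, {
      perm <- sample.int(n)
    })
    val_idx <- perm[seq_len(n_val)]
    idx <- perm[-seq_len(n_val)]
    if (!length(idx)) stop_fmt("validation split leaves no training patches")
  }

  state <- adam_init(model$params)
  params <- model$params
  history <- numeric(cfg$epochs)
  t_step <- 0L
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- idx[sample.int(length(idx))]
      batch_losses <- c()
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        b <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        xb <- x_all[, , , b, drop = FALSE]
        yb <- y_all[, , , b, drop = FALSE]
        fw <- nn_forward(model$plan, params, xb, train = TRUE)
        loss <- bce_from_logits(fw$out, yb)
        if (!is.finite(loss)) {
          stop_fmt("training diverged: non-finite loss at epoch %d", epoch)
        }
        batch_losses <- c(batch_losses, loss)
        grads <- nn_backward(model$plan, params, fw$cache, fw$out, yb)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, t_step, lr = cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      if (length(val_idx)) {
        xv <- x_all[, , , val_idx, drop = FALSE]
        yv <- y_all[, , , val_idx, drop = FALSE]
        fw <- nn_forward(model$plan, params, xv, train = TRUE)
        history[epoch] <- bce_from_logits(fw$out, yv)
      } else {
        history[epoch] <- mean(batch_losses)
      }
      if (!is.finite(history[epoch])) {
        stop_fmt("training diverged: non-finite loss at epoch %d", epoch)
      }
    }
  })
  model$params <- params
  model$loss_history <- c(model$loss_history, history)
  model$trained <- TRUE
  model
}

# Predict probabilities for a batch of normalized patches (H, W, N array).
predict_patches <- function(model, patches) {
  d <- dim(patches)
  x <- array(patches, c(d[1], d[2], 1, d[3]))
  fw <- nn_forward(model$plan, model$params, x, train = FALSE)
  array(pmin(pmax(fw$out, 0), 1), c(d[1], d[2], d[3]))
}

# Reflective padding of a matrix to at least (H, W).
pad_reflect <- function(m, H, W) {
  while (nrow(m) < H) {
    k <- min(nrow(m), H - nrow(m))
    m <- rbind(m, m[nrow(m):(nrow(m) - k + 1), , drop = FALSE])
  }
  while (ncol(m) < W) {
    k <- min(ncol(m), W - ncol(m))
    m <- cbind(m, m[, ncol(m):(ncol(m) - k + 1), drop = FALSE])
  }
  m
}

tile_starts <- function(n, box, stride) {
  s <- seq(1L, n - box + 1L, by = stride)
  if (s[length(s)] != n - box + 1L) s <- c(s, n - box + 1L)
  s
}

#' Segment a volume slice by slice
#'
#' Each z-slice is tiled into `box_size` patches on a `stride` grid (plus a
#' final flush tile per axis), every patch is normalized and predicted, and
#' overlapping predictions are blended by uniform averaging. Slices smaller
#' than the box are reflectively padded and the output cropped back.
#'
#' @param model a trained `seg_model`.
#' @param volume a [volume3d()].
#' @param stride tile stride in pixels, `1 <= stride <= box_size`; the
#'   default `box_size / 2` gives 2x overlap.
#' @param batch_size patches per forward pass.
#' @return A prediction [volume3d()] with values in `[0, 1]`, same shape.
#' @export
segment_volume <- function(model, volume, stride = NULL, batch_size = 64) {
  stopifnot(inherits(model, "seg_model"), is_volume3d(volume))
  box <- model$box_size
  stride <- stride %||% (box %/% 2)
  if (stride < 1 || stride > box) {
    stop_fmt("stride must be in 1..box_size (%d)", box)
  }
  d <- dim(volume$data)
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    sl <- volume$data[, , z]
    H <- max(d[1], box); W <- max(d[2], box)
    if (H != d[1] || W != d[2]) sl <- pad_reflect(sl, H, W)
    xs <- tile_starts(H, box, stride)
    ys <- tile_starts(W, box, stride)
    tiles <- expand.grid(x = xs, y = ys)
    acc <- matrix(0, H, W)
    cnt <- matrix(0, H, W)
    for (start in seq(1, nrow(tiles), by = batch_size)) {
      rows <- start:min(start + batch_size - 1, nrow(tiles))
      patches <- array(0, c(box, box, length(rows)))
      for (j in seq_along(rows)) {
        x0 <- tiles$x[rows[j]]; y0 <- tiles$y[rows[j]]
        patches[, , j] <- normalize_patch(sl[x0:(x0 + box - 1),
                                             y0:(y0 + box - 1)])
      }
      pr <- predict_patches(model, patches)
      for (j in seq_along(rows)) {
        x0 <- tiles$x[rows[j]]; y0 <- tiles$y[rows[j]]
        ix <- x0:(x0 + box - 1); iy <- y0:(y0 + box - 1)
        acc[ix, iy] <- acc[ix, iy] + pr[, , j]
        cnt[ix, iy] <- cnt[ix, iy] + 1
      }
    }
    out[, , z] <- (acc / cnt)[seq_len(d[1]), seq_len(d[2])]
  }
  as_volume_like(out, volume)
}

#' Save / load a model bundle
#'
#' A bundle is a directory with `meta.json` (architecture name, box size,
#' feature name, training pixel size, default threshold, loss history) and
#' `weights.bin` (the flattened parameters), so bundles are self-describing.
#'
#' @param model a `seg_model`.
#' @param dir bundle directory (created if needed).
#' @return `dir` (or, for `load_model`, the restored `seg_model`).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "seg_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(arch_name = model$arch_name, box_size = model$box_size,
               feature_name = model$feature_name,
               training_pixel_size = model$training_pixel_size,
               default_threshold = model$default_threshold,
               loss_history = model$loss_history, trained = model$trained)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  w <- unlist(lapply(model$params, function(p) {
    if (is.null(p)) NULL else c(as.vector(p$w), p$b)
  }))
  con <- file(file.path(dir, "weights.bin"), "wb")
  writeBin(w, con, size = 8L, endian = "little")
  close(con)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  model <- build_model(meta$arch_name, box_size = meta$box_size,
                       feature_name = meta$feature_name,
                       pixel_size = meta$training_pixel_size)
  wfile <- file.path(dir, "weights.bin")
  n <- file.info(wfile)$size / 8
  con <- file(wfile, "rb")
  w <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  close(con)
  pos <- 0L
  for (i in seq_along(model$params)) {
    p <- model$params[[i]]
    if (is.null(p)) next
    nw <- length(p$w); nb <- length(p$b)
    model$params[[i]]$w <- matrix(w[pos + seq_len(nw)], nrow(p$w), ncol(p$w))
    model$params[[i]]$b <- w[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  if (pos != length(w)) stop_fmt("weights.bin does not match architecture")
  model$default_threshold <- meta$default_threshold
  model$loss_history <- as.numeric(meta$loss_history %||% numeric())
  model$trained <- isTRUE(meta$trained)
  model
}

#' Tidy the training history of a model
#'
#' @param x a `seg_model`.
#' @param ... unused.
#' @return A tibble with columns `epoch` and `loss`.
#' @importFrom generics tidy
#' @method tidy seg_model
#' @export
tidy.seg_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a model
#'
#' @param x a `seg_model`.
#' @param ... unused.
#' @return A one-row tibble: architecture, box size, parameter count, epochs
#'   trained and final loss.
#' @importFrom generics glance
#' @method glance seg_model
#' @export
glance.seg_model <- function(x, ...) {
  tibble::tibble(arch_name = x$arch_name, box_size = x$box_size,
                 n_parameters = count_parameters(x),
                 epochs = length(x$loss_history),
                 final_loss = if (length(x$loss_history))
                   utils::tail(x$loss_history, 1) else NA_real_)
}

# re-export the broom-style generics so users need not attach generics
#' @export
generics::tidy

#' @export
generics::glance
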