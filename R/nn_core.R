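# Minimal CNN engine for 2D patch segmentation.
#
# A network is a list of layer specs evaluated sequentially:
#   conv: 3x3 same-padded convolution + activation ("relu", "sigmoid",
#         "linear"); optional `save` tag exposes its output to a later concat.
#   pool: 2x2 max pooling, stride 2.
#   up:   2x nearest-neighbour upsampling; optional `concat` tag appends a
#         previously saved tensor along the channel axis (U-Net skip).
# The last layer must be a conv with sigmoid activation, which keeps every
# prediction in [0, 1]. Training minimises pixel-wise binary cross-entropy
# computed on the logits for numerical stability.

conv_spec <- function(filters, activation = "relu", save = NULL,
                      concat = NULL) {
  list(type = "conv", filters = filters, activation = activation,
       save = save, concat = concat)
}
pool_spec <- function() list(type = "pool")
up_spec <- function(concat = NULL) list(type = "up", concat = concat)

# Walk the specs computing per-layer input channel counts; errors on
# malformed graphs (unknown concat tag, non-sigmoid final layer).
nn_plan <- function(layers) {
  ch <- 1L
  saved <- list()
  plan <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    sp <- layers[[i]]
    if (sp$type == "conv") {
      plan[[i]] <- list(type = "conv", cin = ch, cout = sp$filters,
                        activation = sp$activation, save = sp$save)
      ch <- sp$filters
      if (!is.null(sp$save)) saved[[sp$save]] <- ch
    } else if (sp$type == "pool") {
      plan[[i]] <- list(type = "pool")
    } else if (sp$type == "up") {
      extra <- 0L
      if (!is.null(sp$concat)) {
        if (is.null(saved[[sp$concat]])) {
          stop_fmt("concat tag '%s' was never saved", sp$concat)
        }
        extra <- saved[[sp$concat]]
      }
      plan[[i]] <- list(type = "up", concat = sp$concat)
      ch <- ch + extra
    } else stop_fmt("unknown layer type '%s'", sp$type)
  }
  last <- plan[[length(plan)]]
  if (!identical(last$type, "conv") || !identical(last$activation, "sigmoid")) {
    stop_fmt("the final layer must be a sigmoid conv (output in [0, 1])")
  }
  plan
}

nn_init_params <- function(plan, seed = NULL) {
  init <- function() {
    lapply(plan, function(p) {
      if (p$type != "conv") return(NULL)
      fan_in <- 9 * p$cin
      list(w = matrix(rnorm(fan_in * p$cout, sd = sqrt(2 / fan_in)),
                      fan_in, p$cout),
           b = numeric(p$cout))
    })
  }
  if (is.null(seed)) init() else with_seed(seed, init())
}

sigmoid <- function(z) 1 / (1 + exp(-z))

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass. x: array (H, W, 1, N). Returns list(out, cache); in training
# mode `out` is the final-layer logits, otherwise sigmoid probabilities.
nn_forward <- function(plan, params, x, train = FALSE) {
  cache <- if (train) vector("list", length(plan))
  saved <- list()
  nlay <- length(plan)
  for (i in seq_len(nlay)) {
    p <- plan[[i]]
    if (p$type == "conv") {
      fwc <- cpp_conv3x3_fw(x, params[[i]]$w, params[[i]]$b, train)
      z <- fwc$out
      if (train) cache[[i]] <- list(cols = fwc$cols, xdim = dim(x), z = z)
      x <- if (i == nlay) {
        if (train) z else array(sigmoid(z), dim = dim(z))
      } else if (p$activation == "relu") {
        array(pmax(z, 0), dim = dim(z))
      } else if (p$activation == "sigmoid") {
        array(sigmoid(z), dim = dim(z))
      } else z
      if (!is.null(p$save)) saved[[p$save]] <- x
    } else if (p$type == "pool") {
      r <- cpp_maxpool2_fw(x)
      if (train) cache[[i]] <- list(argmax = r$argmax, xdim = dim(x))
      x <- r$out
    } else { # up
      xdim <- dim(x)
      x <- cpp_upsample2_fw(x)
      if (!is.null(p$concat)) {
        s <- saved[[p$concat]]
        if (train) cache[[i]] <- list(xdim = xdim, c_up = dim(x)[3],
                                      tag = p$concat)
        x <- concat_channels(x, s)
      } else if (train) cache[[i]] <- list(xdim = xdim, c_up = dim(x)[3],
                                           tag = NULL)
    }
  }
  list(out = x, cache = cache, saved = saved)
}

# Stable mean binary cross-entropy from logits.
bce_from_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

# Backward pass from logits. Returns list(grads) matching params, where each
# conv entry has $w and $b. y has the same dim as the logits.
nn_backward <- function(plan, params, cache, logits, y) {
  n_px <- length(logits)
  g <- array((sigmoid(logits) - y) / n_px, dim = dim(logits))
  grads <- vector("list", length(plan))
  pending <- list() # save-tag -> grad accumulated from concat uses
  for (i in rev(seq_along(plan))) {
    p <- plan[[i]]
    if (p$type == "conv") {
      if (!is.null(p$save) && !is.null(pending[[p$save]])) {
        g <- g + pending[[p$save]]
        pending[[p$save]] <- NULL
      }
      cc <- cache[[i]]
      if (i < length(plan)) { # activation derivative (final layer handled
        if (p$activation == "relu") {      # directly from the BCE gradient)
          g <- g * (cc$z > 0)
        } else if (p$activation == "sigmoid") {
          s <- sigmoid(cc$z)
          g <- g * s * (1 - s)
        }
        g <- array(g, dim = dim(cc$z))
      }
      bw <- cpp_conv3x3_bw(cc$cols, cc$xdim, params[[i]]$w, g)
      grads[[i]] <- list(w = bw$gw, b = bw$gb)
      g <- bw$gx
    } else if (p$type == "pool") {
      cc <- cache[[i]]
      g <- cpp_maxpool2_bw(g, cc$argmax, cc$xdim)
    } else { # up
      cc <- cache[[i]]
      if (!is.null(cc$tag)) {
        c_up <- cc$c_up
        g_saved <- g[, , (c_up + 1):dim(g)[3], , drop = FALSE]
        pending[[cc$tag]] <- if (is.null(pending[[cc$tag]])) g_saved
                             else pending[[cc$tag]] + g_saved
        g <- g[, , seq_len(c_up), , drop = FALSE]
      }
      g <- cpp_upsample2_bw(g, cc$xdim)
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mw = p$w * 0, vw = p$w * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(params, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    s <- state[[i]]
    g <- grads[[i]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[i]]$w <- params[[i]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}
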