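# Architecture registry, parameter counting, training, and tiling inference.

tiny_training_set <- function(n = 24, box = 16, seed = 3,
                              blank_labels = FALSE) {
  set.seed(seed)
  images <- array(rnorm(box * box * n, sd = 0.2), c(box, box, n))
  labels <- array(0, c(box, box, n))
  for (i in seq_len(n)) {
    if (!blank_labels && i %% 2 == 1) {
      cx <- sample(5:(box - 5), 1)
      cy <- sample(5:(box - 5), 1)
      images[(cx - 2):(cx + 2), (cy - 2):(cy + 2), i] <-
        images[(cx - 2):(cx + 2), (cy - 2):(cy + 2), i] + 2
      labels[(cx - 2):(cx + 2), (cy - 2):(cy + 2), i] <- 1
    }
  }
  structure(list(feature_name = "blob", box_size = box, images = images,
                 labels = labels, pixel_size = 10,
                 counts = c(n_positive = n / 2, n_negative = n / 2)),
            class = "training_set")
}

test_that("built models honour the input/output contract", {
  for (arch in c("eman2", "vgg", "unet")) {
    m <- build_model(arch, 64, seed = 1)
    x <- array(rnorm(64 * 64), c(64, 64, 1))
    pr <- tomoseg:::predict_patches(m, x)
    expect_equal(dim(pr), c(64, 64, 1))
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("unknown architectures and bad box sizes give helpful errors", {
  expect_error(build_model("nonexistent", 64), "eman2.*unet|unet.*eman2")
  expect_error(build_model("unet", 30), "downsampling factor")
})

test_that("same seed gives identical initial predictions, different differs", {
  x <- array(rnorm(32 * 32), c(32, 32, 1))
  a <- tomoseg:::predict_patches(build_model("vgg", 32, seed = 5), x)
  b <- tomoseg:::predict_patches(build_model("vgg", 32, seed = 5), x)
  d <- tomoseg:::predict_patches(build_model("vgg", 32, seed = 6), x)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("count_parameters equals independent per-layer shape summation", {
  # one 3x3 conv 1->8 with bias: 3*3*1*8 + 8 = 80; stacking 8->8: + 584
  register_architecture("tiny_count", downsample_factor = 1,
                        overwrite = TRUE, build = function(box_size) {
    list(tomoseg:::conv_spec(8, "relu"), tomoseg:::conv_spec(1, "sigmoid"))
  })
  m <- build_model("tiny_count", 16)
  expect_equal(count_parameters(m), 80 + (9 * 8 * 1 + 1))

  # registered U-Net: recompute from the channel plan by brute force
  u <- build_model("unet", 64)
  manual <- 0L
  for (p in u$plan) {
    if (p$type == "conv") manual <- manual + 9L * p$cin * p$cout + p$cout
  }
  expect_equal(count_parameters(u), manual)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(11)
  m <- build_model("unet", 8, seed = 2)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
  fw <- tomoseg:::nn_forward(m$plan, m$params, x, train = TRUE)
  grads <- tomoseg:::nn_backward(m$plan, m$params, fw$cache, fw$out, y)
  loss_at <- function(params) {
    f <- tomoseg:::nn_forward(m$plan, params, x, train = TRUE)
    tomoseg:::bce_from_logits(f$out, y)
  }
  eps <- 1e-6
  for (li in c(1, 3, 7, 10)) {
    if (is.null(m$params[[li]])) next
    for (wi in c(1, length(m$params[[li]]$w))) {
      p2 <- m$params
      p2[[li]]$w[wi] <- p2[[li]]$w[wi] + eps
      num <- (loss_at(p2) - loss_at(m$params)) / eps
      expect_equal(grads[[li]]$w[wi], num, tolerance = 1e-3)
    }
    p2 <- m$params
    p2[[li]]$b[1] <- p2[[li]]$b[1] + eps
    num <- (loss_at(p2) - loss_at(m$params)) / eps
    expect_equal(grads[[li]]$b[1], num, tolerance = 1e-3)
  }
})

test_that("training reduces the loss and records one loss per epoch", {
  ts <- tiny_training_set()
  m <- build_model("eman2", 16, seed = 1)
  m7 <- train_model(m, ts, train_config(epochs = 7, batch_size = 8, seed = 2))
  expect_length(m7$loss_history, 7)
  expect_lt(tail(m7$loss_history, 1), m7$loss_history[1])
  expect_true(m7$trained)
})

test_that("all-zero labels drive mean predictions toward zero", {
  ts <- tiny_training_set(blank_labels = TRUE)
  m <- build_model("eman2", 16, seed = 1)
  m <- train_model(m, ts, train_config(epochs = 10, batch_size = 8, seed = 2,
                                       learning_rate = 1e-2))
  pr <- tomoseg:::predict_patches(m, ts$images)
  expect_lt(mean(pr), 0.1)
})

test_that("training is reproducible and supports a validation split", {
  ts <- tiny_training_set()
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 9)
  a <- train_model(build_model("eman2", 16, seed = 4), ts, cfg)
  b <- train_model(build_model("eman2", 16, seed = 4), ts, cfg)
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$params, b$params)

  cfgv <- train_config(epochs = 3, batch_size = 8, seed = 9,
                       validation_split = 0.25)
  v <- train_model(build_model("eman2", 16, seed = 4), ts, cfgv)
  expect_length(v$loss_history, 3)
  # validation losses come from held-out patches, so they differ from the
  # training losses of the full-set run
  expect_false(identical(v$loss_history, a$loss_history))
})

test_that("segment_volume tiles, blends, and preserves shape and range", {
  ts <- tiny_training_set()
  m <- train_model(build_model("eman2", 16, seed = 1), ts,
                   train_config(epochs = 3, batch_size = 8, seed = 2))

  # slice exactly box-sized with stride = box: single-patch prediction
  v1 <- volume3d(array(rnorm(16 * 16 * 2), c(16, 16, 2)))
  out1 <- segment_volume(m, v1, stride = 16)
  direct <- tomoseg:::predict_patches(
    m, array(tomoseg:::normalize_patch(v1$data[, , 1]), c(16, 16, 1)))
  expect_equal(out1$data[, , 1], direct[, , 1], tolerance = 1e-12)

  # constant inputs: per-patch normalization maps any constant level to the
  # same zero patch, so two constant volumes give identical outputs and all
  # slices agree (patch-border effects are averaged identically everywhere)
  vc5 <- volume3d(array(5, c(40, 40, 2)))
  vc9 <- volume3d(array(-9, c(40, 40, 2)))
  outc5 <- segment_volume(m, vc5, stride = 8)
  outc9 <- segment_volume(m, vc9, stride = 8)
  expect_identical(outc5$data, outc9$data)
  expect_identical(outc5$data[, , 1], outc5$data[, , 2])

  # smaller than the box: reflective padding then crop back
  vs <- volume3d(array(rnorm(10 * 12 * 2), c(10, 12, 2)))
  outs <- segment_volume(m, vs, stride = 16)
  expect_equal(dim(outs$data), c(10, 12, 2))
  expect_true(all(outs$data >= 0 & outs$data <= 1))
})

test_that("model bundles round-trip through disk", {
  ts <- tiny_training_set()
  m <- train_model(build_model("unet", 16, seed = 1, feature_name = "blob",
                               pixel_size = 12.5),
                   ts, train_config(epochs = 2, batch_size = 8, seed = 2))
  dir <- file.path(tempdir(), "bundle")
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "meta.json")))
  m2 <- load_model(dir)
  expect_identical(m2$feature_name, "blob")
  expect_equal(m2$training_pixel_size, 12.5)
  expect_equal(m2$loss_history, m$loss_history)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  expect_equal(tomoseg:::predict_patches(m2, x),
               tomoseg:::predict_patches(m, x))
})

test_that("plugin files in a directory are auto-registered", {
  dir <- file.path(tempdir(), "plugins")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(
    "architecture <- list(",
    "  name = 'plugin_micro',",
    "  downsample_factor = 1,",
    "  build = function(box_size) list(conv_spec(4, 'relu'),",
    "                                  conv_spec(1, 'sigmoid'))",
    ")"), file.path(dir, "micro.R"))
  got <- load_architecture_plugins(dir)
  expect_true("plugin_micro" %in% got)
  expect_true("plugin_micro" %in% list_architectures())
  m <- build_model("plugin_micro", 16, seed = 1)
  expect_equal(count_parameters(m), 9 * 4 + 4 + 9 * 4 + 1)
})

test_that("tidy and glance summarise fitted models", {
  ts <- tiny_training_set()
  m <- train_model(build_model("eman2", 16, seed = 1), ts,
                   train_config(epochs = 4, batch_size = 8, seed = 2))
  td <- tidy(m)
  expect_equal(td$epoch, 1:4)
  expect_equal(td$loss, m$loss_history)
  gl <- glance(m)
  expect_equal(gl$epochs, 4L)
  expect_equal(gl$n_parameters, count_parameters(m))
})
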