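# Colocalization / avoidance interactions and model competition.

pred_vol <- function(arr, px = 10) volume3d(arr, voxel_size = px)

test_that("full and empty parent masks are identity edge cases", {
  set.seed(1)
  child <- pred_vol(array(runif(21 * 21 * 2), c(21, 21, 2)))
  ones <- pred_vol(array(1, c(21, 21, 2)))
  zeros <- pred_vol(array(0, c(21, 21, 2)))
  co <- interaction_spec("p", "c", "colocalize", 0.5, radius_nm = 5)
  av <- interaction_spec("p", "c", "avoid", 0.5, radius_nm = 5)
  expect_equal(apply_interaction(child, ones, co)$data, child$data)
  expect_equal(apply_interaction(child, zeros, av)$data, child$data)
  # and the opposite pairings suppress everything
  expect_true(all(apply_interaction(child, zeros, co)$data == 0))
  expect_true(all(apply_interaction(child, ones, av)$data == 0))
})

test_that("a single above-threshold parent voxel keeps exactly the R-disk", {
  child <- pred_vol(array(1, c(21, 21, 1)), px = 10)
  parent <- pred_vol(array(0, c(21, 21, 1)), px = 10)
  parent$data[11, 11, 1] <- 0.9
  # R = 2 px at 10 A/px -> radius_nm = 2 px * 1 nm/px
  spec <- interaction_spec("p", "c", "colocalize", 0.5, radius_nm = 2)
  out <- apply_interaction(child, parent, spec)
  kept <- which(out$data == 1)
  # brute-force disk membership: dx^2 + dy^2 <= 4 has 13 lattice points
  co <- arrayInd(kept, dim(out$data))
  expect_identical(length(kept), 13L)
  expect_true(all((co[, 1] - 11)^2 + (co[, 2] - 11)^2 <= 4))
  expect_true(all(out$data %in% c(0, 1)))
})

test_that("avoidance clears a full R-band around a carbon-like plane", {
  # carbon occupies x >= 31 (0-based 30); membrane child is ones
  d <- c(40, 24, 2)
  parent <- pred_vol(array(0, d), px = 10)
  parent$data[31:40, , ] <- 1
  child <- pred_vol(array(1, d), px = 10)
  spec <- interaction_spec("carbon", "membrane", "avoid", 0.5,
                           radius_nm = 10) # 10 nm at 1 nm/px -> 10 px
  out <- apply_interaction(child, parent, spec)
  # brute-force distance check per voxel
  for (x in 1:40) {
    expected <- if ((31 - x) <= 10) 0 else 1
    expect_true(all(out$data[x, , ] == expected))
  }
})

test_that("interactions and competition are suppression-only", {
  set.seed(2)
  d <- c(16, 16, 3)
  for (i in 1:5) {
    child <- pred_vol(array(runif(prod(d)), d))
    parent <- pred_vol(array(runif(prod(d)), d))
    for (kind in c("colocalize", "avoid")) {
      sp <- interaction_spec("p", "c", kind, runif(1), runif(1, 0, 4))
      out <- apply_interaction(child, parent, sp)
      expect_true(all(out$data <= child$data + 1e-12))
    }
    preds <- list(a = child, b = parent)
    outp <- apply_competition(preds, competition_config(c("a", "b"),
                                                        c("a", "b")))
    expect_true(all(outp$a$data <= child$data))
    expect_true(all(outp$b$data <= parent$data))
  }
})

test_that("colocalize grows and avoid shrinks monotonically with R", {
  set.seed(3)
  d <- c(20, 20, 2)
  child <- pred_vol(array(runif(prod(d)), d))
  parent <- pred_vol(array(runif(prod(d)) * (runif(prod(d)) < 0.05), d))
  prev_co <- NULL
  prev_av <- NULL
  for (r in c(0, 1, 2, 4, 8)) {
    co <- apply_interaction(child, parent,
                            interaction_spec("p", "c", "colocalize", 0.5, r))
    av <- apply_interaction(child, parent,
                            interaction_spec("p", "c", "avoid", 0.5, r))
    if (!is.null(prev_co)) {
      expect_true(all(co$data >= prev_co$data))
      expect_true(all(av$data <= prev_av$data))
    }
    prev_co <- co
    prev_av <- av
  }
})

test_that("dilated masks equal the per-voxel distance-check oracle", {
  set.seed(4)
  for (i in 1:4) {
    d <- c(sample(8:32, 1), sample(8:32, 1), sample(2:6, 1))
    parent <- array(runif(prod(d)) * (runif(prod(d)) < 0.08), d)
    thr <- 0.3
    for (r in c(1, 3, 5)) {
      got <- tomoseg:::dilated_mask(parent, thr, r, kernel_3d = FALSE)
      want <- oracle_dilate_slicewise(parent, thr, r)
      expect_identical(got & TRUE, want)
    }
  }
})

test_that("competition uses strict inequality and simultaneous semantics", {
  d <- c(4, 4, 1)
  mk <- function(val) pred_vol(array(val, d))
  both <- competition_config(c("a", "b"), c("a", "b"))

  out <- apply_competition(list(a = mk(0.7), b = mk(0.3)), both)
  expect_true(all(out$a$data == 0.7))
  expect_true(all(out$b$data == 0))

  tie <- apply_competition(list(a = mk(0.5), b = mk(0.5)), both)
  expect_true(all(tie$a$data == 0.5)) # ties preserved: needs strictly higher
  expect_true(all(tie$b$data == 0.5))

  # one-way: a absorbs but does not emit; b emits only -> b never modified
  oneway <- competition_config(emitting = "b", absorbing = "a")
  out1 <- apply_competition(list(a = mk(0.4), b = mk(0.6)), oneway)
  expect_true(all(out1$a$data == 0))
  expect_true(all(out1$b$data == 0.6))
  out2 <- apply_competition(list(a = mk(0.8), b = mk(0.6)), oneway)
  expect_true(all(out2$a$data == 0.8))

  # simultaneous update: all comparisons against original inputs, so the
  # result is invariant under feature order
  set.seed(5)
  preds <- list(a = pred_vol(array(runif(16), d)),
                b = pred_vol(array(runif(16), d)),
                c = pred_vol(array(runif(16), d)))
  cfg <- competition_config(c("a", "b", "c"), c("a", "b", "c"))
  o1 <- apply_competition(preds, cfg)
  o2 <- apply_competition(rev(preds), cfg)
  for (f in names(preds)) expect_equal(o1[[f]]$data, o2[[f]]$data)
  # and matches the per-voxel rule evaluated directly
  for (f in names(preds)) {
    rival <- do.call(pmax, lapply(preds[setdiff(names(preds), f)],
                                  function(v) v$data))
    want <- preds[[f]]$data
    want[rival > want] <- 0
    expect_equal(o1[[f]]$data, want)
  }
})

test_that("competition is idempotent", {
  set.seed(6)
  d <- c(10, 10, 4)
  preds <- list(a = pred_vol(array(runif(prod(d)), d)),
                b = pred_vol(array(runif(prod(d)), d)))
  cfg <- competition_config(c("a", "b"), c("a", "b"))
  once <- apply_competition(preds, cfg)
  twice <- apply_competition(once, cfg)
  for (f in names(preds)) expect_equal(once[[f]]$data, twice[[f]]$data)
})

test_that("pipelines compose competition then ordered interactions", {
  d <- c(30, 10, 1)
  child <- pred_vol(array(1, d), px = 10)
  pa <- pred_vol(array(0, d), px = 10)
  pa$data[10, 5, 1] <- 1
  pb <- pred_vol(array(0, d), px = 10)
  pb$data[20, 5, 1] <- 1
  preds <- list(target = child, a = pa, b = pb)

  expect_equal(apply_pipeline(preds)$target$data, child$data) # identity

  i1 <- interaction_spec("a", "target", "colocalize", 0.5, 3)
  i2 <- interaction_spec("b", "target", "colocalize", 0.5, 3)
  # colocalizing with two disjoint parents in sequence annihilates the child
  r12 <- apply_pipeline(preds, interactions = list(i1, i2))$target
  expect_true(all(r12$data == 0))

  # order sensitivity: when an interaction edits a feature that a later
  # interaction uses as parent, the two orders differ (the Fig-3C-style
  # chain structure: edit the membrane first, then colocalize with it)
  ia <- interaction_spec("b", "a", "avoid", 0.5, 3)        # edits a
  ib <- interaction_spec("a", "target", "colocalize", 0.5, 3) # reads a
  preds2 <- list(target = pred_vol(array(1, d)),
                 a = pred_vol(array(1, d)), b = pb)
  r_edit_first <- apply_pipeline(preds2, interactions = list(ia, ib))$target
  r_read_first <- apply_pipeline(preds2, interactions = list(ib, ia))$target
  expect_false(identical(r_edit_first$data, r_read_first$data))
  # reading the unedited parent (all ones) leaves the target untouched
  expect_true(all(r_read_first$data == 1))
  # editing first carves the avoided band out of the target's mask
  expect_true(any(r_edit_first$data == 0))

  expect_error(apply_pipeline(preds, interactions = list(
    interaction_spec("missing", "target", "avoid"))), "missing")
})

test_that("interaction specs validate their fields", {
  expect_error(interaction_spec("x", "x", "avoid"), "differ")
  expect_error(interaction_spec("a", "b", "avoid", parent_threshold = 1.2),
               "0, 1")
  expect_error(interaction_spec("a", "b", "avoid", radius_nm = -1), ">= 0")
  expect_error(apply_interaction(pred_vol(array(0, c(4, 4, 1))),
                                 pred_vol(array(0, c(5, 5, 1))),
                                 interaction_spec("a", "b", "avoid")),
               "shape")
})

test_that("both avoidance border conventions are available and differ", {
  d <- c(20, 9, 1)
  parent <- pred_vol(array(0, d), px = 10)
  parent$data[10:20, , 1] <- 1
  child <- pred_vol(array(1, d), px = 10)
  sp <- interaction_spec("p", "c", "avoid", 0.5, radius_nm = 3)
  after <- apply_interaction(child, parent, sp)
  before <- apply_interaction(child, parent, sp,
                              avoid_mode = "complement_before")
  # complement-after suppresses the R-band outside the mask; complement-
  # before keeps an R-band inside it
  expect_true(all(after$data[7:9, , 1] == 0))
  expect_true(all(before$data[7:9, , 1] == 1))
  expect_true(all(after$data[1:6, , 1] == 1))
  expect_true(all(before$data[13:20, , 1] == 0))
})
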