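test_that("backbone stages halve the spatial size and are deterministic", {
  model <- init_cascade(backbone_config(), seed = 3)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  bb <- backbone_forward(img, model$scales[[1]], model$cfg)
  sizes <- vapply(bb$features, function(f) dim(f)[1], numeric(1))
  expect_equal(sizes, c(32, 16, 8, 4, 2))
  expect_equal(vapply(bb$features, function(f) dim(f)[3], numeric(1)),
               as.numeric(model$cfg$channels))
  bb2 <- backbone_forward(img, model$scales[[1]], model$cfg)
  expect_identical(bb$features, bb2$features)
  expect_error(backbone_forward(array(0, c(32, 32, 3)), model$scales[[1]],
                                model$cfg), "expects")
})

test_that("all-zero convolution parameters give spatially constant stages", {
  model <- init_cascade(backbone_config(), seed = 3)
  zp <- lapply(model$scales[[1]]$stages, function(st)
    list(W = st$W * 0, b = st$b * 0 + 0.3))
  sp <- model$scales[[1]]
  sp$stages <- zp
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  bb <- backbone_forward(img, sp, model$cfg)
  for (f in bb$features) {
    rng <- apply(f, 3, function(sl) max(sl) - min(sl))
    expect_equal(max(rng), 0)
  }
})

test_that("pool heads emit simplex vectors; zero parameters give uniform", {
  model <- init_cascade(backbone_config(), seed = 5)
  feat <- array(runif(4 * 4 * 16), c(4, 4, 16))
  zero_head <- list(W = matrix(0, 4, 16), b = numeric(4))
  expect_equal(pool_head_predict(feat, zero_head), rep(0.25, 4))
  set.seed(6)
  for (r in 1:100) {
    head <- list(W = matrix(rnorm(4 * 16), 4, 16), b = rnorm(4))
    p <- pool_head_predict(feat, head)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("permuting head rows permutes the probability vector identically", {
  feat <- array(runif(4 * 4 * 8), c(4, 4, 8))
  set.seed(9)
  head <- list(W = matrix(rnorm(5 * 8), 5, 8), b = rnorm(5))
  p <- pool_head_predict(feat, head)
  perm <- c(3, 1, 5, 2, 4)
  permuted <- list(W = head$W[perm, ], b = head$b[perm])
  expect_equal(pool_head_predict(feat, permuted), p[perm],
               tolerance = 1e-12)
})

test_that("APN boxes are always valid and sit at the centre for zero params", {
  cfg <- backbone_config()
  crop <- crop_config(out_size = 64)
  feat <- array(runif(2 * 2 * 32), c(2, 2, 32))
  zero_apn <- list(W1 = matrix(0, 16, 32), b1 = numeric(16),
                   W2 = matrix(0, 3, 16), b2 = numeric(3))
  box0 <- apn_predict(feat, zero_apn, crop, 64)
  expect_equal(box0$tx, 31.5)
  expect_equal(box0$ty, 31.5)
  expect_equal(box0$tl, (8 + 0.45 * 32) / 2)  # mid-range half length
  set.seed(10)
  for (r in 1:50) {
    apn <- list(W1 = matrix(rnorm(16 * 32, 0, 2), 16, 32), b1 = rnorm(16),
                W2 = matrix(rnorm(3 * 16, 0, 2), 3, 16), b2 = rnorm(3))
    b <- apn_predict(feat, apn, crop, 64)
    co <- box_corners(b)
    expect_gte(co["tx_tl"], 0); expect_lte(co["tx_br"], 63)
    expect_gte(co["ty_tl"], 0); expect_lte(co["ty_br"], 63)
    expect_gte(b$tl, crop$min_half_len)
    expect_lte(b$tl, 0.45 * 32 + 1e-12)
  }
})

test_that("APN output varies continuously with its input", {
  crop <- crop_config(out_size = 64)
  set.seed(11)
  apn <- list(W1 = matrix(rnorm(16 * 32, 0, 0.5), 16, 32), b1 = rnorm(16),
              W2 = matrix(rnorm(3 * 16, 0, 0.5), 3, 16), b2 = rnorm(3))
  feat <- array(runif(2 * 2 * 32), c(2, 2, 32))
  b0 <- apn_predict(feat, apn, crop, 64)
  deltas <- 10^seq(-3, -6)
  drift <- vapply(deltas, function(d) {
    f2 <- feat + array(d, dim(feat))
    b1 <- apn_predict(f2, apn, crop, 64)
    abs(b1$tx - b0$tx) + abs(b1$ty - b0$ty) + abs(b1$tl - b0$tl)
  }, numeric(1))
  expect_true(all(diff(drift) < 0))   # shrinking perturbation, shrinking drift
  expect_lt(drift[4], 1e-4)
})

test_that("cascade runs on degenerate input and keeps every simplex", {
  model <- init_cascade(backbone_config(), seed = 13)
  gray <- array(0.5, c(64, 64, 3))
  fwd <- cascade_forward(gray, model)
  expect_length(fwd$scales, 3)
  for (s in fwd$scales) {
    for (p in s$pool_probs) {
      expect_equal(sum(p), 1, tolerance = 1e-6)
      expect_true(all(p >= 0))
    }
    co <- box_corners(s$box)
    expect_true(co["tx_tl"] >= 0 && co["tx_br"] <= 63)
  }
  expect_equal(sum(fwd$fused_prob), 1, tolerance = 1e-6)
})

test_that("scale m+1 consumes exactly the crop of scale m's box", {
  model <- init_cascade(backbone_config(), seed = 14)
  # non-trivial boxes: randomise the APN
  set.seed(14)
  for (m in 1:3) {
    model$scales[[m]]$apn$W2[] <- rnorm(48, 0, 1)
    model$scales[[m]]$apn$b2 <- rnorm(3)
  }
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fwd <- cascade_forward(img, model)
  for (m in 1:2) {
    expected <- crop_and_zoom(fwd$scales[[m]]$input, fwd$scales[[m]]$box,
                              model$crop)
    expect_identical(fwd$scales[[m + 1]]$input, expected)
  }
  expect_identical(fwd$scales[[1]]$input, img)
})

test_that("an oracle APN box yields a magnified view of the patch", {
  sp <- scene_spec(clutter_density = 0, noise_sd = 0)
  set.seed(15)
  img <- generate_scene(sp, 0)
  tb <- img$truth_box
  stopifnot(tb$tl <= 16)  # <= input_size / 4: at least 2x magnification
  crop <- crop_config(steepness = 1e4, out_size = 64, min_half_len = 2)
  zoomed <- crop_and_zoom(img$pixels, tb, crop)
  # magnification factor out_size / (2 tl) >= 2: the patch fills the view;
  # its grating structure must appear (non-constant interior)
  interior <- zoomed[16:48, 16:48, 1]
  expect_gt(max(interior) - min(interior), 0.2)
  # and a far-background crop of the same size is constant
  far <- attention_box(
    if (tb$tx > 31.5) tb$tl + 1 else 62 - tb$tl - 1,
    if (tb$ty > 31.5) tb$tl + 1 else 62 - tb$ty - 1, tb$tl)
  # guard: only meaningful if the boxes do not overlap
  if (box_iou(far, tb) == 0) {
    bg <- crop_and_zoom(img$pixels, far, crop)[16:48, 16:48, 1]
    expect_lt(max(bg) - min(bg), 1e-6)
  }
})

test_that("soft vote is the exact convex combination", {
  v <- list(c(0.6, 0.3, 0.1), c(0.2, 0.2, 0.6), c(0.1, 0.8, 0.1))
  w <- c(0.5, 0.3, 0.2)
  ref <- 0.5 * v[[1]] + 0.3 * v[[2]] + 0.2 * v[[3]]
  expect_equal(soft_vote(v, w), ref, tolerance = 1e-12)
  expect_equal(soft_vote(v, c(1, 0, 0)), v[[1]])
  expect_equal(soft_vote(rep(list(c(0.3, 0.7)), 4), rep(0.25, 4)),
               c(0.3, 0.7))
  expect_error(soft_vote(v, c(0.5, 0.5)), "one weight per")
  expect_error(soft_vote(v, c(0.9, 0.2, -0.1)), "sum to 1")
})

test_that("evaluation-mode forward is deterministic, training mode stochastic", {
  model <- init_cascade(backbone_config(), seed = 16)
  # make heads sensitive to dropout
  set.seed(16)
  for (i in 1:5)
    model$scales[[3]]$heads[[i]]$W[] <-
      rnorm(length(model$scales[[3]]$heads[[i]]$W))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  e1 <- cascade_forward(img, model)
  e2 <- cascade_forward(img, model)
  expect_identical(e1$fused_prob, e2$fused_prob)
  set.seed(1); t1 <- cascade_forward(img, model, train_mode = TRUE)
  set.seed(2); t2 <- cascade_forward(img, model, train_mode = TRUE)
  expect_false(identical(t1$fused_prob, t2$fused_prob))
})
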