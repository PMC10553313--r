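test_that("scene generation is deterministic and respects its configuration", {
  sp <- scene_spec(seed = 7)
  set.seed(7); a <- generate_scene(sp, 1)
  set.seed(7); b <- generate_scene(sp, 1)
  expect_identical(a, b)
  expect_equal(dim(a$pixels), c(64, 64, 3))
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  expect_equal(a$label, 1L)
  co <- box_corners(a$truth_box)
  expect_gte(co["tx_tl"], 0); expect_lte(co["tx_br"], 63)
  expect_gte(co["ty_tl"], 0); expect_lte(co["ty_br"], 63)
  expect_error(generate_scene(sp, 4), "out of range")
  expect_error(scene_spec(patch_half_len_range = c(8, 40)), "below")
})

test_that("with no clutter and no noise only the patch differs from background", {
  sp <- scene_spec(clutter_density = 0, noise_sd = 0)
  set.seed(12)
  img <- generate_scene(sp, 2)
  px <- img$pixels
  box <- img$truth_box
  outside <- outer(0:63, 0:63, function(y, x)
    abs(x - box$tx) > box$tl | abs(y - box$ty) > box$tl)
  bgvals <- px[, , 1][outside]
  expect_equal(max(bgvals) - min(bgvals), 0, tolerance = 1e-12)
  # the patch region carries structure
  inside_var <- var(as.numeric(px[, , 1][!outside]))
  expect_gt(inside_var, 1e-3)
})

test_that("the planted patch, and only the patch, is class-discriminative", {
  skip_if_not_installed("nnet")
  sp <- scene_spec(seed = 123)
  set.seed(123)
  n_per <- 200
  samples <- list()
  for (cl in 0:3)
    for (i in 1:n_per)
      samples[[length(samples) + 1]] <- generate_scene(sp, cl)
  y <- factor(vapply(samples, function(s) s$label, numeric(1)))
  down <- function(px)  # whole-image downsample to 12x12
    as.numeric(crop_and_zoom(px, attention_box(31.5, 31.5, 31.5),
                             crop_config(steepness = 1e6, out_size = 12,
                                         min_half_len = 1, max_frac = 1)))
  # features: the truth-box crop, zoomed to a fixed small size
  crop_feats <- t(vapply(samples, function(s) {
    as.numeric(crop_and_zoom(s$pixels, s$truth_box,
                             crop_config(steepness = 1e6, out_size = 12,
                                         min_half_len = 1)))
  }, numeric(12 * 12 * 3)))
  # features: the whole image with the patch blanked out
  blank_feats <- t(vapply(samples, function(s) {
    px <- s$pixels
    b <- s$truth_box
    m <- hard_box_indicator(b, 64, 64)
    for (ch in 1:3) px[, , ch][m > 0] <- 0.5
    down(px)
  }, numeric(12 * 12 * 3)))
  idx <- sample(length(samples))
  tr <- idx[1:600]; te <- idx[601:800]
  fit1 <- nnet::multinom(y ~ ., data.frame(y = y[tr], crop_feats[tr, ]),
                         trace = FALSE, MaxNWts = 5000, maxit = 120)
  acc1 <- mean(predict(fit1, data.frame(crop_feats[te, ])) == y[te])
  fit2 <- nnet::multinom(y ~ ., data.frame(y = y[tr], blank_feats[tr, ]),
                         trace = FALSE, MaxNWts = 5000, maxit = 120)
  acc2 <- mean(predict(fit2, data.frame(blank_feats[te, ])) == y[te])
  expect_gt(acc1, 0.9)    # patch crops are highly discriminative
  expect_lt(acc2, 0.45)   # patchless images are near chance (0.25)
})

test_that("mirror augmentations are involutions and transform the box", {
  sp <- scene_spec(seed = 5)
  set.seed(5)
  img <- generate_scene(sp, 0)
  twice <- augment(augment(img, "mirror_h"), "mirror_h")
  expect_equal(twice$pixels, img$pixels)
  expect_equal(twice$truth_box, img$truth_box)
  once_v <- augment(img, "mirror_v")
  expect_equal(once_v$truth_box$ty, 63 - img$truth_box$ty)
  expect_equal(once_v$truth_box$tx, img$truth_box$tx)
  expect_equal(once_v$truth_box$tl, img$truth_box$tl)
  expect_identical(augment(img, character()), img)  # empty ops: identity
  expect_error(augment(img, "sharpen"), "unknown")
})

test_that("brightness never changes the label and factor 1 is the identity", {
  sp <- scene_spec(seed = 9)
  set.seed(9)
  img <- generate_scene(sp, 3)
  b <- augment(img, "brightness", brightness_range = c(1, 1))
  expect_equal(b$pixels, img$pixels, tolerance = 1e-14)
  set.seed(1)
  for (r in 1:10) {
    a <- augment(img, c("rotate", "mirror_h", "brightness"))
    expect_equal(a$label, img$label)
    expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  }
})

test_that("right-angle rotation moves the truth box with the patch", {
  sp <- scene_spec(clutter_density = 0, noise_sd = 0)
  set.seed(31)
  img <- generate_scene(sp, 1)
  set.seed(99)
  rot <- augment(img, "rotate", angles = 90)
  # the rotated truth box must still cover the (rotated) patch: pixels
  # outside it are constant background
  box <- rot$truth_box
  outside <- outer(0:63, 0:63, function(y, x)
    abs(x - box$tx) > box$tl + 1 | abs(y - box$ty) > box$tl + 1)
  bg <- rot$pixels[, , 2][outside]
  expect_equal(max(bg) - min(bg), 0, tolerance = 1e-12)
  # free-angle rotation drops the box
  set.seed(100)
  free <- augment(img, "rotate", free_angle = TRUE)
  expect_null(free$truth_box)
})

test_that("stratified split hits the 6:3:1 counts and partitions the input", {
  fake <- function(label, id)
    structure(list(label = label, id = id), class = "labeled_image")
  one_class <- lapply(1:1000, function(i) fake(0, i))
  sp <- split_dataset(one_class, seed = 1)
  expect_equal(lengths(sp), c(train = 600, validation = 300, test = 100))

  multi <- list()
  for (cl in 0:3) for (i in 1:100)
    multi[[length(multi) + 1]] <- fake(cl, paste0(cl, "-", i))
  sp2 <- split_dataset(multi, seed = 2)
  for (part in names(sp2)) {
    labs <- vapply(sp2[[part]], function(s) s$label, numeric(1))
    expect_equal(unname(table(labs)),
                 rep(c(train = 60, validation = 30, test = 10)[[part]], 4),
                 ignore_attr = TRUE)
  }
  ids <- sort(unname(unlist(lapply(sp2, function(p)
    vapply(p, function(s) s$id, character(1))))))
  expect_equal(ids, sort(vapply(multi, function(s) s$id, character(1))))

  expect_warning(
    split_dataset(c(lapply(1:12, function(i) fake(0, i)),
                    list(fake(1, "x"), fake(1, "y"))), seed = 1),
    "best-effort")
})

test_that("split proportions stay within one sample of 6:3:1 across cases", {
  fake <- function(label, id)
    structure(list(label = label, id = id), class = "labeled_image")
  set.seed(17)
  for (r in 1:200) {
    n_classes <- sample(1:5, 1)
    sizes <- sample(5:40, n_classes, replace = TRUE)
    samples <- list()
    for (cl in seq_len(n_classes) - 1)
      for (i in seq_len(sizes[cl + 1]))
        samples[[length(samples) + 1]] <- fake(cl, paste0(cl, ".", i))
    if (length(samples) < 10) next
    sp <- suppressWarnings(split_dataset(samples, seed = r))
    expect_equal(sum(lengths(sp)), length(samples))
    for (cl in seq_len(n_classes) - 1) {
      n <- sizes[cl + 1]
      got <- vapply(sp, function(p)
        sum(vapply(p, function(s) s$label, numeric(1)) == cl), numeric(1))
      expect_true(all(abs(got - n * c(0.6, 0.3, 0.1)) <= 1))
    }
    ids <- unname(unlist(lapply(sp, function(p)
      vapply(p, function(s) s$id, character(1)))))
    expect_equal(sort(ids),
                 sort(vapply(samples, function(s) s$id, character(1))))
  }
})

test_that("box IoU is exact on hand-positioned squares", {
  a <- attention_box(10, 10, 5)   # [5,15]^2, area 100
  expect_equal(box_iou(a, a), 1)
  b <- attention_box(20, 10, 5)   # just touching: zero overlap
  expect_equal(box_iou(a, b), 0)
  c <- attention_box(15, 10, 5)   # [10,20]x[5,15]: overlap 5x10 = 50
  expect_equal(box_iou(a, c), 50 / (100 + 100 - 50))
})
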