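#' Scene specification for the synthetic planted-patch benchmark
#'
#' The generator emulates a fine-grained pest photo gallery at desk scale:
#' every image carries exactly one localised class-discriminative patch (an
#' oriented sinusoidal grating whose orientation, spatial frequency and hue
#' are determined by the class) embedded in a cluttered background of
#' distractor blobs that share the patch colour statistics but not the
#' grating texture. Discriminative information is therefore confined to the
#' patch, which is what makes attention-localisation tests meaningful.
#'
#' @param image_size Pixels per side (square images). Default 64 for
#'   desk-scale runs; use 224 for the full-scale configuration.
#' @param n_classes Number of classes, at least 2.
#' @param patch_half_len_range Integer `(min, max)` half side length of the
#'   planted patch, in pixels; `max` must be below `image_size / 2`.
#' @param clutter_density Expected number of distractor blobs per image.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed recorded with the scene configuration.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = 64, n_classes = 4,
                       patch_half_len_range = c(8, 14),
                       clutter_density = 8, noise_sd = 0.02, seed = 1L) {
  stopifnot(image_size >= 16, n_classes >= 2,
            length(patch_half_len_range) == 2,
            patch_half_len_range[1] >= 2,
            patch_half_len_range[1] <= patch_half_len_range[2],
            clutter_density >= 0, noise_sd >= 0)
  if (patch_half_len_range[2] >= image_size / 2)
    stop("patch_half_len_range max must be below image_size / 2")
  structure(list(image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 patch_half_len_range = as.integer(patch_half_len_range),
                 clutter_density = clutter_density, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Distinct, saturated class colours; classes beyond 8 reuse hues with a
# brightness offset.
class_palette <- function(n) {
  base <- rbind(c(0.9, 0.2, 0.2), c(0.2, 0.75, 0.25), c(0.2, 0.35, 0.9),
                c(0.85, 0.75, 0.15), c(0.8, 0.25, 0.8), c(0.15, 0.8, 0.8),
                c(0.9, 0.55, 0.2), c(0.5, 0.3, 0.1))
  idx <- ((seq_len(n) - 1) %% nrow(base)) + 1
  shift <- 0.12 * ((seq_len(n) - 1) %/% nrow(base))
  pmin(pmax(base[idx, , drop = FALSE] + shift, 0), 1)
}

# Per-class grating parameters: orientation, spatial frequency (cycles/px).
class_texture_params <- function(n) {
  list(theta = pi * (seq_len(n) - 1) / n,
       freq = 0.08 + 0.05 * ((seq_len(n) - 1) %% 4))
}

#' Generate one labelled scene
#'
#' Draws a background level, plants `clutter_density` (Poisson) distractor
#' blobs, then a single class-discriminative grating patch at a uniform
#' random location, adds Gaussian noise and clips to `[0, 1]`. Uses the
#' current R random-number stream: seed it (`set.seed()`) for determinism.
#'
#' @param spec A [scene_spec()].
#' @param class_id Integer class index in `[0, n_classes)`.
#' @return A `labeled_image`: list with `pixels` (`H x W x 3` array in
#'   `[0, 1]`), `label` (0-based integer), `truth_box` (an
#'   [attention_box()] over the planted patch), `split_tag` (`NA` until
#'   assigned).
#' @export
generate_scene <- function(spec, class_id) {
  if (class_id < 0 || class_id >= spec$n_classes)
    stop("class_id out of range [0, n_classes)")
  n <- spec$image_size
  pal <- class_palette(spec$n_classes)
  tex <- class_texture_params(spec$n_classes)

  bg <- runif(1, 0.35, 0.65)
  img <- array(bg, c(n, n, 3))
  xg <- matrix(rep(0:(n - 1), each = n), n, n)   # x along columns
  yg <- matrix(rep(0:(n - 1), times = n), n, n)  # y along rows

  n_blobs <- rpois(1, spec$clutter_density)
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 0, n - 1); cy <- runif(1, 0, n - 1)
    rx <- runif(1, 3, 9); ry <- runif(1, 3, 9); phi <- runif(1, 0, pi)
    col <- pal[sample.int(spec$n_classes, 1), ]
    dx <- xg - cx; dy <- yg - cy
    u <- cos(phi) * dx + sin(phi) * dy
    v <- -sin(phi) * dx + cos(phi) * dy
    alpha <- 0.6 * exp(-((u / rx)^2 + (v / ry)^2))
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alpha) + col[ch] * alpha
  }

  hl <- sample(seq(spec$patch_half_len_range[1],
                   spec$patch_half_len_range[2]), 1)
  tx <- runif(1, hl, (n - 1) - hl)
  ty <- runif(1, hl, (n - 1) - hl)
  theta <- tex$theta[class_id + 1]; freq <- tex$freq[class_id + 1]
  phase <- runif(1, 0, 2 * pi)
  col <- pal[class_id + 1, ]
  xs <- max(0, floor(tx - hl)):min(n - 1, ceiling(tx + hl))
  ys <- max(0, floor(ty - hl)):min(n - 1, ceiling(ty + hl))
  for (x in xs) {
    proj <- cos(theta) * (x - tx) + sin(theta) * (ys - ty)
    # multiplicative grating over the class colour: the patch mean stays
    # class-coloured (a linear hue signal) while the stripes carry the
    # class orientation and frequency
    g <- 0.55 + 0.45 * sin(2 * pi * freq * proj + phase)
    inside <- abs(x - tx) <= hl & abs(ys - ty) <= hl
    for (ch in 1:3) {
      val <- col[ch] * g
      old <- img[ys + 1, x + 1, ch]
      img[ys + 1, x + 1, ch] <- ifelse(inside, val, old)
    }
  }

  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)

  structure(list(pixels = img, label = as.integer(class_id),
                 truth_box = attention_box(tx, ty, hl),
                 split_tag = NA_character_),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %dx%d, label %d, split %s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$label,
              ifelse(is.na(x$split_tag), "unassigned", x$split_tag)))
  invisible(x)
}

#' Augment a labelled image
#'
#' Applies each requested operation with randomly drawn parameters:
#' rotation (right angles by default, so the truth box stays exact; free
#' angles drop the truth box), horizontal/vertical mirroring, and a
#' multiplicative brightness factor. The class label is never altered and
#' output intensities are clipped to `[0, 1]`.
#'
#' @param image A `labeled_image`.
#' @param ops Character subset of
#'   `c("rotate", "mirror_h", "mirror_v", "brightness")`; empty means
#'   identity.
#' @param angles Rotation angles sampled from when `free_angle = FALSE`.
#' @param brightness_range Range the brightness factor is drawn from.
#' @param free_angle If `TRUE`, draw the rotation angle uniformly from
#'   `[0, 360)` (bilinear resampling; truth box dropped).
#' @return The augmented `labeled_image`.
#' @export
augment <- function(image, ops = character(),
                    angles = c(90, 180, 270),
                    brightness_range = c(0.7, 1.3), free_angle = FALSE) {
  bad <- setdiff(ops, c("rotate", "mirror_h", "mirror_v", "brightness"))
  if (length(bad)) stop("unknown augmentation op(s): ",
                        paste(bad, collapse = ", "))
  px <- image$pixels
  box <- image$truth_box
  H <- dim(px)[1]; W <- dim(px)[2]

  if ("mirror_h" %in% ops) {          # flip left-right: x -> W-1-x
    px <- px[, W:1, , drop = FALSE]
    if (!is.null(box)) box$tx <- (W - 1) - box$tx
  }
  if ("mirror_v" %in% ops) {          # flip top-bottom: y -> H-1-y
    px <- px[H:1, , , drop = FALSE]
    if (!is.null(box)) box$ty <- (H - 1) - box$ty
  }
  if ("rotate" %in% ops) {
    if (free_angle) {
      ang <- runif(1, 0, 360)
      px <- cpp_rotate_bilinear(px, ang, fill = 0.5)
      box <- NULL
    } else {
      ang <- sample(angles, 1)
      k <- (round(ang / 90) %% 4)
      for (q in seq_len(k)) {         # 90-degree clockwise steps
        px <- rot90_cw(px)
        if (!is.null(box)) {
          new_tx <- (H - 1) - box$ty; new_ty <- box$tx
          box$tx <- new_tx; box$ty <- new_ty
        }
      }
    }
  }
  if ("brightness" %in% ops) {
    f <- runif(1, brightness_range[1], brightness_range[2])
    px <- px * f
  }
  px <- pmin(pmax(px, 0), 1)
  out <- image
  out$pixels <- px
  out$truth_box <- box
  out
}

rot90_cw <- function(a) {
  H <- dim(a)[1]
  out <- array(0, c(dim(a)[2], H, dim(a)[3]))
  for (ch in seq_len(dim(a)[3]))
    out[, , ch] <- t(a[H:1, , ch])
  out
}

#' Stratified 6:3:1 split
#'
#' Partitions samples per class into train/validation/test in the given
#' ratio. Within each class the floor counts are assigned first and the
#' rounding remainder goes to train, then validation, then test.
#' Deterministic given `seed`.
#'
#' @param samples List of `labeled_image` (or any list elements carrying a
#'   `label` field).
#' @param seed Integer seed for the within-class shuffle.
#' @param ratios Numeric length-3 split ratio (normalised internally).
#' @return List with elements `train`, `validation`, `test`; each sample's
#'   `split_tag` is set accordingly.
#' @export
split_dataset <- function(samples, seed = 1L, ratios = c(6, 3, 1)) {
  stopifnot(length(samples) >= 10)
  labels <- vapply(samples, function(s) s$label, numeric(1))
  ratios <- ratios / sum(ratios)
  assign <- character(length(samples))
  rng <- local_rng(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 3)
      warning(sprintf("class %s has %d < 3 samples; best-effort assignment",
                      format(cl), length(idx)))
    idx <- idx[rng$sample_perm(length(idx))]
    n <- length(idx)
    k <- floor(ratios * n)
    rem <- n - sum(k)
    if (rem > 0)
      k[seq_len(rem)] <- k[seq_len(rem)] + 1  # train, then val, then test
    tags <- rep(c("train", "validation", "test"), times = k)
    assign[idx] <- tags
  }
  out <- list(train = list(), validation = list(), test = list())
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    s$split_tag <- assign[i]
    key <- assign[i]
    out[[key]][[length(out[[key]]) + 1L]] <- s
  }
  out
}

# A private RNG stream that does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    st
  }
  env$sample_perm <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    p <- sample.int(n)
    env$state <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    p
  }
  env
}

#' Generate a full split dataset
#'
#' Convenience wrapper generating `n_train + n_validation + n_test` fresh
#' scenes per class and tagging them with their split. Deterministic given
#' the spec seed (seeds the R stream internally).
#'
#' @param spec A [scene_spec()].
#' @param n_train,n_validation,n_test Images per class and split. The
#'   defaults (200/100/35) are the desk-scale study condition,
#'   approximating a 6:3:1 regime.
#' @return List with `train`, `validation`, `test` lists of
#'   `labeled_image`.
#' @export
generate_dataset <- function(spec, n_train = 200, n_validation = 100,
                             n_test = 35) {
  set.seed(spec$seed)
  out <- list(train = list(), validation = list(), test = list())
  counts <- c(train = n_train, validation = n_validation, test = n_test)
  for (split in names(counts)) {
    for (cl in 0:(spec$n_classes - 1)) {
      for (i in seq_len(counts[[split]])) {
        s <- generate_scene(spec, cl)
        s$split_tag <- split
        out[[split]][[length(out[[split]]) + 1L]] <- s
      }
    }
  }
  out
}

#' Intersection over union of two square boxes
#'
#' @param a,b [attention_box()] objects.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ca <- box_corners(a); cb <- box_corners(b)
  ix <- max(0, min(ca["tx_br"], cb["tx_br"]) - max(ca["tx_tl"], cb["tx_tl"]))
  iy <- max(0, min(ca["ty_br"], cb["ty_br"]) - max(ca["ty_tl"], cb["ty_tl"]))
  inter <- ix * iy
  union <- (2 * a$tl)^2 + (2 * b$tl)^2 - inter
  unname(inter / union)
}

#' @importFrom stats rpois
NULL
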