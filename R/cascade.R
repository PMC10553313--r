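#' Backbone configuration
#'
#' Each scale of the cascade uses a five-stage VGG-style stack: every stage
#' is a 3x3 convolution (stride 1, zero padding 1), ReLU, and 2x2 max
#' pooling, so stage `i` halves the spatial size. Five stages are
#' load-bearing: the five pooling-level predictions P1..P5 they induce are
#' the inputs to the soft-voting fusion stage.
#'
#' @param input_size Input side length in pixels; must be divisible by 32.
#' @param channels Integer vector of 5 output channel counts. The default
#'   is the desk-scale (64-pixel) configuration; widen (e.g.
#'   `c(16, 32, 64, 64, 64)`) for larger inputs.
#' @param n_classes Number of classes.
#' @param dropout_rate Dropout applied to each pooled feature vector before
#'   its prediction head's affine map (training mode only).
#' @param apn_hidden Hidden width of the attention-proposal head.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(input_size = 64, channels = c(8, 16, 32, 64, 64),
                            n_classes = 4, dropout_rate = 0.45,
                            apn_hidden = 32) {
  stopifnot(length(channels) == 5, all(channels >= 1),
            input_size %% 32 == 0, n_classes >= 2,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_stages = 5L, input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 apn_hidden = as.integer(apn_hidden)),
            class = "backbone_config")
}

init_stage <- function(c_in, c_out) {
  # He initialisation for the ReLU convolutions
  list(W = matrix(rnorm(9 * c_in * c_out, 0, sqrt(2 / (9 * c_in))),
                  9 * c_in, c_out),
       b = numeric(c_out))
}

# Readout layers start at zero: the untrained model then predicts exactly
# uniform probabilities (heads) and a centred mid-range box (APN), and the
# first Adam steps learn a clean discriminant direction instead of
# correcting random initial logits.
init_head <- function(c_in, n_classes) {
  list(W = matrix(0, n_classes, c_in), b = numeric(n_classes))
}

init_apn <- function(c_in, hidden) {
  list(W1 = matrix(rnorm(hidden * c_in, 0, 0.3), hidden, c_in),
       b1 = numeric(hidden),
       W2 = matrix(0, 3, hidden),
       b2 = numeric(3))
}

#' Initialise a three-scale cascade model
#'
#' The three scales have identical architecture but independent parameters
#' (optionally shared with `share_backbone = TRUE`, in which case scale 1's
#' parameter set is used by all scales).
#'
#' @param cfg A [backbone_config()].
#' @param crop A [crop_config()]; its `out_size` must equal
#'   `cfg$input_size` so every scale consumes the same resolution.
#' @param seed Integer seed for weight initialisation.
#' @param n_scales Number of scales (fixed at 3).
#' @param share_backbone Share one parameter set across scales.
#' @param fusion_mode Which five predictors feed the fusion stage:
#'   `"across_scales"` (each pooling level averaged over the three
#'   scales — the default, matching the swarm's role of synthesising
#'   information across scales) or `"final_scale"` (the five pooling
#'   heads of scale 3 only).
#' @param aux_loss Add cross-entropy on the four auxiliary pooling heads
#'   during training (off by default; they are otherwise trained only
#'   through the fusion stage).
#' @return A `cascade_model` list.
#' @export
init_cascade <- function(cfg = backbone_config(),
                         crop = crop_config(out_size = cfg$input_size),
                         seed = 1L, n_scales = 3L, share_backbone = FALSE,
                         fusion_mode = c("across_scales", "final_scale"),
                         aux_loss = FALSE) {
  fusion_mode <- match.arg(fusion_mode)
  if (crop$out_size != cfg$input_size)
    stop("crop out_size must equal backbone input_size")
  set.seed(seed)
  chans <- c(3L, cfg$channels)
  make_scale <- function() {
    list(stages = lapply(1:5, function(i) init_stage(chans[i], chans[i + 1])),
         heads = lapply(1:5, function(i) init_head(cfg$channels[i],
                                                   cfg$n_classes)),
         apn = init_apn(cfg$channels[5], cfg$apn_hidden))
  }
  scales <- lapply(seq_len(n_scales), function(m) make_scale())
  if (share_backbone) for (m in seq_len(n_scales)) scales[[m]] <- scales[[1]]
  structure(list(cfg = cfg, crop = crop, n_scales = as.integer(n_scales),
                 share_backbone = share_backbone, fusion_mode = fusion_mode,
                 aux_loss = aux_loss, scales = scales, seed = as.integer(seed)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(paste0("<cascade_model> %d scales, input %dx%d, channels %s, ",
                     "%d classes, fusion %s\n"),
              x$n_scales, x$cfg$input_size, x$cfg$input_size,
              paste(x$cfg$channels, collapse = "/"), x$cfg$n_classes,
              x$fusion_mode))
  invisible(x)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

gap <- function(feat) {
  d <- dim(feat)
  colMeans(matrix(feat, d[1] * d[2], d[3]))
}

#' Backbone forward pass
#'
#' Runs the five conv/ReLU/pool stages of one scale's backbone and returns
#' the five post-pooling feature maps (stage `i` has spatial side
#' `input_size / 2^i`).
#'
#' @param image `input_size x input_size x 3` array.
#' @param scale_params One element of `model$scales`.
#' @param cfg The model's [backbone_config()].
#' @param keep_cache Retain intermediate buffers for the backward pass.
#' @return List with `features` (5 arrays) and, if requested, `caches`.
#' @export
backbone_forward <- function(image, scale_params, cfg, keep_cache = FALSE) {
  image <- as_image_array(image)
  if (dim(image)[1] != cfg$input_size || dim(image)[2] != cfg$input_size)
    stop(sprintf("input is %dx%d but backbone expects %dx%d",
                 dim(image)[1], dim(image)[2], cfg$input_size,
                 cfg$input_size))
  feats <- vector("list", 5)
  caches <- if (keep_cache) vector("list", 5) else NULL
  x <- image
  for (i in 1:5) {
    st <- scale_params$stages[[i]]
    res <- cpp_conv_pool_forward(x, st$W, st$b)
    feats[[i]] <- res$out
    if (keep_cache)
      caches[[i]] <- list(act = res$act, cols = res$cols,
                          argmax = res$argmax, in_dim = dim(x))
    x <- res$out
  }
  list(features = feats, caches = caches)
}

#' Pooling-level prediction head
#'
#' Global average pooling of a feature map followed by an affine map and
#' softmax; the output lies on the class simplex.
#'
#' @param feature_map A stage output from [backbone_forward()].
#' @param head_params List with `W` (`n_classes x channels`) and `b`.
#' @return Class-probability vector.
#' @export
pool_head_predict <- function(feature_map, head_params) {
  g <- gap(feature_map)
  softmax(drop(head_params$W %*% g + head_params$b))
}

# Squash three raw APN outputs into a valid box. tl lands in
# [min_half_len, max_frac * side/2]; the centre is then confined so the
# square always lies inside the image. At raw = 0 the box sits at the
# image centre with mid-range tl.
apn_squash <- function(raw, input_size, crop) {
  s <- plogis(raw)
  wm1 <- input_size - 1
  tl_min <- crop$min_half_len
  tl_max <- crop$max_frac * input_size / 2
  tl <- tl_min + s[3] * (tl_max - tl_min)
  tx <- tl + s[1] * (wm1 - 2 * tl)
  ty <- tl + s[2] * (wm1 - 2 * tl)
  attention_box(tx, ty, tl)
}

#' Attention-proposal head
#'
#' A small regression head (global pooling, two affine layers with a tanh
#' in between) on the deepest feature map; its three raw outputs are
#' squashed into a valid [attention_box()] (centre inside the image, half
#' length within configured bounds), so any parameter setting yields a
#' usable crop.
#'
#' @param deepest_feature_map Stage-5 output of [backbone_forward()].
#' @param apn_params List with `W1, b1, W2, b2`.
#' @param crop A [crop_config()].
#' @param input_size Side length of the image the box refers to.
#' @return An [attention_box()].
#' @export
apn_predict <- function(deepest_feature_map, apn_params, crop, input_size) {
  g <- gap(deepest_feature_map)
  a1 <- tanh(drop(apn_params$W1 %*% g + apn_params$b1))
  raw <- drop(apn_params$W2 %*% a1 + apn_params$b2)
  apn_squash(raw, input_size, crop)
}

# Forward pass of one scale; returns predictions, box, and caches.
scale_forward <- function(image, sp, cfg, crop, train_mode = FALSE) {
  bb <- backbone_forward(image, sp, cfg, keep_cache = train_mode)
  rate <- if (train_mode) cfg$dropout_rate else 0
  head_caches <- vector("list", 5)
  pool_probs <- vector("list", 5)
  for (i in 1:5) {
    g <- gap(bb$features[[i]])
    mask <- if (rate > 0) {
      (runif(length(g)) >= rate) / (1 - rate)
    } else rep(1, length(g))
    gd <- g * mask
    p <- softmax(drop(sp$heads[[i]]$W %*% gd + sp$heads[[i]]$b))
    pool_probs[[i]] <- p
    head_caches[[i]] <- list(g = g, mask = mask, gd = gd, p = p)
  }
  g5 <- gap(bb$features[[5]])
  a1 <- tanh(drop(sp$apn$W1 %*% g5 + sp$apn$b1))
  raw <- drop(sp$apn$W2 %*% a1 + sp$apn$b2)
  box <- apn_squash(raw, cfg$input_size, crop)
  list(pool_probs = pool_probs, scale_prob = pool_probs[[5]], box = box,
       cache = list(backbone = bb, heads = head_caches,
                    apn = list(g5 = g5, a1 = a1, raw = raw),
                    feat_dims = lapply(bb$features, dim)))
}

#' Full cascade forward pass
#'
#' Scale 1 consumes the input image; each scale's attention box is cropped
#' and zoomed ([crop_and_zoom()]) to the network input size and fed to the
#' next scale. Per-scale parameters are independent. The fused probability
#' is the soft vote of the five fusion predictors (see `fusion_mode` in
#' [init_cascade()]) under `weights` (uniform by default).
#'
#' @param image `input_size x input_size x 3` array in `[0, 1]`.
#' @param model A [init_cascade()] model.
#' @param weights Fusion weights (length 5, nonnegative, summing to 1).
#' @param train_mode Enable dropout and retain backward caches. In
#'   evaluation mode (default) the pass is deterministic.
#' @param true_label Optional 0-based label; fills `true_class_conf` per
#'   scale.
#' @return A `cascade_output`: `scales` (each with `pool_probs` P1..P5,
#'   `scale_prob` = P5, `box`, `input` image), and `fused_prob`.
#' @export
cascade_forward <- function(image, model, weights = NULL,
                            train_mode = FALSE, true_label = NULL) {
  if (is.null(weights)) weights <- rep(1 / 5, 5)
  image <- as_image_array(image)
  scales <- vector("list", model$n_scales)
  x <- image
  for (m in seq_len(model$n_scales)) {
    sf <- scale_forward(x, model$scales[[m]], model$cfg, model$crop,
                        train_mode)
    sf$input <- x
    if (!is.null(true_label))
      sf$true_class_conf <- sf$scale_prob[true_label + 1]
    scales[[m]] <- sf
    if (m < model$n_scales)
      x <- cpp_crop_zoom(x, sf$box$tx, sf$box$ty, sf$box$tl,
                         model$crop$steepness, model$crop$out_size)
  }
  fused <- soft_vote(fusion_inputs(scales, model$fusion_mode), weights)
  structure(list(scales = scales, fused_prob = fused),
            class = "cascade_output")
}

# The five probability vectors that feed the fusion stage.
fusion_inputs <- function(scales, fusion_mode) {
  if (fusion_mode == "final_scale") {
    scales[[length(scales)]]$pool_probs
  } else {
    lapply(1:5, function(i) {
      Reduce(`+`, lapply(scales, function(s) s$pool_probs[[i]])) /
        length(scales)
    })
  }
}

#' Soft voting
#'
#' Weighted arithmetic mean of class-probability vectors; with convex
#' weights the result stays on the simplex.
#'
#' @param prob_vectors List of equal-length probability vectors.
#' @param weights Nonnegative weights summing to 1, one per vector.
#' @return Combined probability vector.
#' @export
soft_vote <- function(prob_vectors, weights) {
  if (length(prob_vectors) != length(weights))
    stop("need exactly one weight per probability vector")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  lens <- vapply(prob_vectors, length, integer(1))
  if (length(unique(lens)) != 1) stop("probability vectors differ in length")
  drop(Reduce(`+`, Map(`*`, prob_vectors, weights)))
}
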