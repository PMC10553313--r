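#' Training configuration
#'
#' Defaults follow the standard recipe for this model family: Adam with
#' initial learning rate 5e-5, batch size 16, up to 45 epochs with the
#' learning rate multiplied by 0.96 each epoch, dropout 0.45, early
#' stopping after 20 epochs without validation improvement, and a ranking
#' margin of 0.05.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Images per gradient step.
#' @param max_epochs Maximum training epochs.
#' @param decay_rate Per-epoch multiplicative learning-rate decay; epoch
#'   `e` (0-based) uses `learning_rate * decay_rate^e`.
#' @param dropout_rate Dropout before each pooling head's affine map.
#' @param early_stop_patience Epochs without validation-accuracy
#'   improvement before stopping.
#' @param rank_margin Hinge margin of the inter-scale ranking loss.
#' @param seed Integer seed governing shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-5, batch_size = 16,
                         max_epochs = 45, decay_rate = 0.96,
                         dropout_rate = 0.45, early_stop_patience = 20,
                         rank_margin = 0.05, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            decay_rate > 0, decay_rate <= 1,
            early_stop_patience >= 1, rank_margin >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 decay_rate = decay_rate, dropout_rate = dropout_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 rank_margin = rank_margin, seed = as.integer(seed)),
            class = "train_config")
}

#' Per-scale classification loss
#'
#' Sum over the three scales of the cross-entropy between each scale's
#' probability vector (the deepest pooling head, P5) and the true label.
#' Probabilities are floored at 1e-12 before taking logs.
#'
#' @param cascade A `cascade_output` from [cascade_forward()].
#' @param true_label 0-based class index.
#' @return Nonnegative scalar.
#' @export
classification_loss <- function(cascade, true_label) {
  sum(vapply(cascade$scales, function(s) {
    -log(max(s$scale_prob[true_label + 1], 1e-12))
  }, numeric(1)))
}

#' Inter-scale ranking loss
#'
#' Hinge `max(0, pt_m - pt_next + margin)` on the true-class probabilities
#' of consecutive scales: zero exactly when the finer scale beats the
#' coarser by at least the margin, so minimising it forces confidence to
#' grow along the cascade.
#'
#' @param pt_m True-class probability at scale `m`.
#' @param pt_next True-class probability at scale `m + 1`.
#' @param margin Nonnegative margin.
#' @return Nonnegative scalar.
#' @export
ranking_loss <- function(pt_m, pt_next, margin = 0.05) {
  stopifnot(pt_m >= 0, pt_m <= 1, pt_next >= 0, pt_next <= 1, margin >= 0)
  max(0, pt_m - pt_next + margin)
}

#' Joint loss
#'
#' Classification loss summed over the three scales plus the ranking loss
#' over the scale pairs (1,2) and (2,3).
#'
#' @inheritParams classification_loss
#' @param margin Ranking margin.
#' @return Nonnegative scalar.
#' @export
total_loss <- function(cascade, true_label, margin = 0.05) {
  pt <- vapply(cascade$scales, function(s) s$scale_prob[true_label + 1],
               numeric(1))
  classification_loss(cascade, true_label) +
    ranking_loss(pt[1], pt[2], margin) + ranking_loss(pt[2], pt[3], margin)
}

# vector-Jacobian product of softmax: d logits given d probs
softmax_vjp <- function(p, dp) p * (dp - sum(p * dp))

# Gradient of global average pooling: spread dg evenly over space.
gap_backward <- function(dg, fdim) {
  array(rep(dg / (fdim[1] * fdim[2]), each = fdim[1] * fdim[2]), fdim)
}

# Backward through the APN squashing + the two affine layers.
apn_backward <- function(dbox, sp, cache, cfg, crop) {
  raw <- cache$apn$raw
  s <- plogis(raw)
  wm1 <- cfg$input_size - 1
  tl_min <- crop$min_half_len
  tl_max <- crop$max_frac * cfg$input_size / 2
  tl <- tl_min + s[3] * (tl_max - tl_min)
  A <- wm1 - 2 * tl
  dtl_tot <- dbox[3] + dbox[1] * (1 - 2 * s[1]) + dbox[2] * (1 - 2 * s[2])
  dr <- c(dbox[1] * s[1] * (1 - s[1]) * A,
          dbox[2] * s[2] * (1 - s[2]) * A,
          dtl_tot * (tl_max - tl_min) * s[3] * (1 - s[3]))
  a1 <- cache$apn$a1
  g5 <- cache$apn$g5
  dW2 <- dr %o% a1
  db2 <- dr
  da1 <- drop(t(sp$apn$W2) %*% dr)
  dz1 <- da1 * (1 - a1^2)
  dW1 <- dz1 %o% g5
  db1 <- dz1
  dg5 <- drop(t(sp$apn$W1) %*% dz1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dg5 = dg5)
}

# Backward pass of one scale. dlogits: list of 5 (NULL = no loss on that
# head). dbox: length-3 gradient arriving at this scale's attention box,
# or NULL. Returns parameter gradients and (optionally) the gradient with
# respect to the scale's input image.
scale_backward <- function(sp, sf, dlogits, dbox, cfg, crop,
                           need_input_grad) {
  cache <- sf$cache
  fdims <- cache$feat_dims
  dfeat <- vector("list", 5)
  head_grads <- vector("list", 5)
  for (i in 1:5) {
    hc <- cache$heads[[i]]
    if (is.null(dlogits[[i]])) {
      head_grads[[i]] <- list(W = sp$heads[[i]]$W * 0,
                              b = sp$heads[[i]]$b * 0)
      next
    }
    dl <- dlogits[[i]]
    head_grads[[i]] <- list(W = dl %o% hc$gd, b = dl)
    dg <- drop(t(sp$heads[[i]]$W) %*% dl) * hc$mask
    dfeat[[i]] <- gap_backward(dg, fdims[[i]])
  }
  apn_grads <- list(W1 = sp$apn$W1 * 0, b1 = sp$apn$b1 * 0,
                    W2 = sp$apn$W2 * 0, b2 = sp$apn$b2 * 0)
  if (!is.null(dbox)) {
    ab <- apn_backward(dbox, sp, cache, cfg, crop)
    apn_grads <- ab$grads
    add5 <- gap_backward(ab$dg5, fdims[[5]])
    dfeat[[5]] <- if (is.null(dfeat[[5]])) add5 else dfeat[[5]] + add5
  }
  stage_grads <- vector("list", 5)
  dcur <- if (is.null(dfeat[[5]])) array(0, fdims[[5]]) else dfeat[[5]]
  for (i in 5:1) {
    bc <- cache$backbone$caches[[i]]
    want_dx <- (i > 1) || need_input_grad
    res <- cpp_conv_pool_backward(dcur, bc$act, bc$cols, bc$argmax,
                                  sp$stages[[i]]$W, bc$in_dim[1],
                                  bc$in_dim[2], want_dx)
    stage_grads[[i]] <- list(W = res$dW, b = drop(res$db))
    if (i > 1) {
      dcur <- res$dX
      if (!is.null(dfeat[[i - 1]])) dcur <- dcur + dfeat[[i - 1]]
    } else if (need_input_grad) {
      dcur <- res$dX
    } else dcur <- NULL
  }
  list(grads = list(stages = stage_grads, heads = head_grads,
                    apn = apn_grads),
       dInput = if (need_input_grad) dcur else NULL)
}

# One training example: forward (with dropout), loss, and gradients for
# every parameter of the cascade, including the paths through
# crop-and-zoom into the attention-proposal heads.
cascade_train_step <- function(model, image, label, margin) {
  fwd <- cascade_forward(image, model, train_mode = TRUE,
                         true_label = label)
  y1 <- label + 1
  C <- model$cfg$n_classes
  onehot <- numeric(C); onehot[y1] <- 1
  pt <- vapply(fwd$scales, function(s) s$scale_prob[y1], numeric(1))
  lcls <- sum(-log(pmax(pt, 1e-12)))
  r12 <- max(0, pt[1] - pt[2] + margin)
  r23 <- max(0, pt[2] - pt[3] + margin)
  dPt <- numeric(3)
  if (r12 > 0) { dPt[1] <- dPt[1] + 1; dPt[2] <- dPt[2] - 1 }
  if (r23 > 0) { dPt[2] <- dPt[2] + 1; dPt[3] <- dPt[3] - 1 }

  scale_dlogits <- lapply(1:3, function(m) {
    p5 <- fwd$scales[[m]]$scale_prob
    dl5 <- (p5 - onehot)
    if (dPt[m] != 0) {
      dp <- numeric(C); dp[y1] <- dPt[m]
      dl5 <- dl5 + softmax_vjp(p5, dp)
    }
    dl <- vector("list", 5)
    if (model$aux_loss)
      for (i in 1:4) dl[[i]] <- fwd$scales[[m]]$pool_probs[[i]] - onehot
    dl[[5]] <- dl5
    dl
  })

  grads <- vector("list", 3)
  dInput_next <- NULL  # gradient w.r.t. the input of scale m+1
  for (m in 3:1) {
    dbox <- NULL
    if (m < 3) {
      cg <- cpp_crop_zoom_backward(fwd$scales[[m]]$input,
                                   fwd$scales[[m]]$box$tx,
                                   fwd$scales[[m]]$box$ty,
                                   fwd$scales[[m]]$box$tl,
                                   model$crop$steepness,
                                   model$crop$out_size, dInput_next)
      dbox <- as.numeric(cg$dbox)
      dX_through_crop <- cg$dX
    }
    sb <- scale_backward(model$scales[[m]], fwd$scales[[m]],
                         scale_dlogits[[m]], dbox, model$cfg, model$crop,
                         need_input_grad = (m > 1))
    grads[[m]] <- sb$grads
    if (m > 1) {
      dInput_next <- sb$dInput
      if (m < 3) dInput_next <- dInput_next + dX_through_crop
    }
  }
  list(grads = grads, lcls = lcls, lrank = r12 + r23,
       loss = lcls + r12 + r23, pt = pt)
}

# ---- nested-list parameter tree helpers -------------------------------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(x, y, f), a, b)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    attributes(out) <- attributes(a)
    out
  } else f(a)
}

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(params = tree_map2(params, upd, `-`), state = state)
}

# Single forward sweep over a sample list collecting everything an epoch
# needs: accuracy of the fused prediction (uniform weights), true-class
# confidences per scale, and scale-1 boxes.
epoch_eval <- function(model, samples, weights = NULL) {
  n <- length(samples)
  correct <- 0
  pt_gap <- numeric(n)
  iou <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    fwd <- cascade_forward(s$pixels, model, weights = weights,
                           true_label = s$label)
    if (which.max(fwd$fused_prob) - 1 == s$label) correct <- correct + 1
    pt <- vapply(fwd$scales, function(sc) sc$scale_prob[s$label + 1],
                 numeric(1))
    pt_gap[i] <- pt[3] - pt[1]
    if (!is.null(s$truth_box))
      iou[i] <- box_iou(fwd$scales[[1]]$box, s$truth_box)
  }
  list(accuracy = correct / n, mean_pt_gap = mean(pt_gap),
       mean_iou = mean(iou, na.rm = TRUE))
}

#' Train the cascade
#'
#' Minimises the joint loss ([total_loss()]) with Adam over mini-batches;
#' the learning rate decays geometrically per epoch; validation accuracy
#' is evaluated each epoch; training stops at `max_epochs` or when
#' validation accuracy has not improved for `early_stop_patience` epochs.
#' The parameters of the best validation epoch are returned. Fully
#' reproducible given `cfg$seed`.
#'
#' The log contains an epoch-0 row describing the untrained model, then
#' one row per trained epoch with mean losses, learning rate, validation
#' accuracy, mean IoU of scale-1 attention boxes against truth boxes
#' (synthetic data), and the mean true-class confidence gap
#' `Pt(3) - Pt(1)` on the validation set.
#'
#' @param model A [init_cascade()] model.
#' @param datasets List with `train` and `validation` lists of
#'   `labeled_image`.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-validation parameters), `log` (a
#'   data.frame), `best_epoch`, and `stop_reason`.
#' @export
train_cascade <- function(model, datasets, cfg = train_config(),
                          verbose = FALSE) {
  if (!length(datasets$train) || !length(datasets$validation))
    stop("train and validation splits must be nonempty")
  model$cfg$dropout_rate <- cfg$dropout_rate
  set.seed(cfg$seed)
  params <- model$scales
  state <- adam_init(params)
  n_tr <- length(datasets$train)

  ev0 <- epoch_eval(model, datasets$validation)
  log <- data.frame(epoch = 0L, lr = cfg$learning_rate, lcls = NA_real_,
                    lrank = NA_real_, loss = NA_real_,
                    val_accuracy = ev0$accuracy, mean_iou = ev0$mean_iou,
                    pt_gap = ev0$mean_pt_gap, seconds = 0)
  # the first trained epoch sets the early-stopping baseline; epoch 0 is
  # recorded for reference only
  best <- list(acc = -Inf, params = params, epoch = 0L)
  since_improve <- 0L
  stop_reason <- "max_epochs"

  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[3]
    lr <- cfg$learning_rate * cfg$decay_rate^(epoch - 1)
    ord <- sample.int(n_tr)
    ep_lcls <- 0; ep_lrank <- 0
    i <- 1
    while (i <= n_tr) {
      idx <- ord[i:min(i + cfg$batch_size - 1, n_tr)]
      gsum <- NULL
      for (j in idx) {
        s <- datasets$train[[j]]
        model$scales <- params
        step <- cascade_train_step(model, s$pixels, s$label,
                                   cfg$rank_margin)
        if (!is.finite(step$loss))
          stop(sprintf("non-finite loss at epoch %d (sample %d)", epoch, j))
        ep_lcls <- ep_lcls + step$lcls
        ep_lrank <- ep_lrank + step$lrank
        g <- step$grads
        if (model$share_backbone) {
          shared <- Reduce(function(a, b) tree_map2(a, b, `+`), g)
          g <- rep(list(shared), model$n_scales)
        }
        gsum <- if (is.null(gsum)) g else tree_map2(gsum, g, `+`)
      }
      gmean <- tree_map(gsum, function(x) x / length(idx))
      upd <- adam_step(params, gmean, state, lr)
      params <- upd$params
      state <- upd$state
      if (model$share_backbone)
        for (m in seq_len(model$n_scales)) params[[m]] <- params[[1]]
      i <- i + cfg$batch_size
    }
    model$scales <- params
    ev <- epoch_eval(model, datasets$validation)
    secs <- proc.time()[3] - t0
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 lcls = ep_lcls / n_tr,
                                 lrank = ep_lrank / n_tr,
                                 loss = (ep_lcls + ep_lrank) / n_tr,
                                 val_accuracy = ev$accuracy,
                                 mean_iou = ev$mean_iou,
                                 pt_gap = ev$mean_pt_gap, seconds = secs))
    if (verbose)
      message(sprintf(
        "epoch %2d lr %.2e loss %.4f val_acc %.3f iou %.3f gap %+.3f (%.1fs)",
        epoch, lr, (ep_lcls + ep_lrank) / n_tr, ev$accuracy, ev$mean_iou,
        ev$mean_pt_gap, secs))
    if (ev$accuracy > best$acc) {
      best <- list(acc = ev$accuracy, params = params, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$early_stop_patience) {
        stop_reason <- "early_stop"
        break
      }
    }
  }
  model$scales <- best$params
  list(model = model, log = log, best_epoch = best$epoch,
       stop_reason = stop_reason)
}

#' Evaluate a model on a sample list
#'
#' Runs [cascade_forward()] on every sample, fuses the five pooling-level
#' predictors under `fusion_weights`, takes the arg-max label
#' (lowest-index tie-break) and delegates to [metrics_report()].
#'
#' @param model A cascade model.
#' @param samples List of `labeled_image`.
#' @param fusion_weights Length-5 convex weights (uniform if `NULL`).
#' @return List with `report` (a `metrics_report`), `predicted` and
#'   `truth` (0-based integer vectors).
#' @export
evaluate_model <- function(model, samples, fusion_weights = NULL) {
  pred <- integer(length(samples))
  truth <- integer(length(samples))
  for (i in seq_along(samples)) {
    fwd <- cascade_forward(samples[[i]]$pixels, model,
                           weights = fusion_weights)
    pred[i] <- which.max(fwd$fused_prob) - 1L
    truth[i] <- samples[[i]]$label
  }
  list(report = metrics_report(truth, pred, model$cfg$n_classes),
       predicted = pred, truth = truth)
}

#' Collect per-head predictions for the fusion stage
#'
#' Forward pass over a sample list recording the five fusion predictors
#' (see `fusion_mode`) for every sample; the input the particle-swarm
#' weight optimiser consumes.
#'
#' @param model A cascade model.
#' @param samples List of `labeled_image`.
#' @return List with `pool_probs` (list of 5 `n x C` matrices) and
#'   `labels` (0-based).
#' @export
collect_pool_probs <- function(model, samples) {
  n <- length(samples)
  C <- model$cfg$n_classes
  mats <- lapply(1:5, function(i) matrix(0, n, C))
  labels <- integer(n)
  for (s in seq_len(n)) {
    fwd <- cascade_forward(samples[[s]]$pixels, model)
    fi <- fusion_inputs(fwd$scales, model$fusion_mode)
    for (i in 1:5) mats[[i]][s, ] <- fi[[i]]
    labels[s] <- samples[[s]]$label
  }
  list(pool_probs = mats, labels = labels)
}
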