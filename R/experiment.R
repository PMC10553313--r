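#' Scale ablation
#'
#' Evaluates every requested subset of scales by uniform soft voting over
#' the member scales' probability vectors (P5 per scale), mirroring the
#' single-scale versus pairwise versus full-cascade comparison. One
#' forward pass per sample is shared across all subsets.
#'
#' @param model A trained (or untrained) cascade model.
#' @param samples List of `labeled_image`.
#' @param subsets List of integer vectors of scale indices.
#' @return A data.frame with one row per subset and columns `model`,
#'   `Acc`, `MPre`, `MRec`, `MF1`, `GM`.
#' @export
ablate_scales <- function(model, samples,
                          subsets = list(1, 2, 3, c(1, 2), c(1, 3),
                                         c(2, 3), c(1, 2, 3))) {
  n <- length(samples)
  C <- model$cfg$n_classes
  probs <- array(0, c(n, C, model$n_scales))
  truth <- integer(n)
  for (i in seq_len(n)) {
    fwd <- cascade_forward(samples[[i]]$pixels, model)
    for (m in seq_len(model$n_scales))
      probs[i, , m] <- fwd$scales[[m]]$scale_prob
    truth[i] <- samples[[i]]$label
  }
  rows <- lapply(subsets, function(ss) {
    fused <- apply(probs[, , ss, drop = FALSE], c(1, 2), mean)
    pred <- max.col(fused, ties.method = "first") - 1L
    rep <- metrics_report(truth, pred, C)
    data.frame(model = paste0("scale ", paste(ss, collapse = "+")),
               Acc = rep$Acc, MPre = rep$MPre, MRec = rep$MRec,
               MF1 = rep$MF1, GM = rep$GM)
  })
  do.call(rbind, rows)
}

#' Desk-scale end-to-end experiment
#'
#' The package's reference experiment: generate the synthetic
#' planted-patch benchmark (4 classes, 64x64, 200/100/35 images per class
#' and split), train the three-scale cascade for `epochs` epochs with the
#' standard optimiser settings, fit fusion weights by PSO on the
#' validation split only, and evaluate on the held-out test split. Also
#' evaluates the untrained model as the baseline, and returns the
#' scale-ablation table.
#'
#' All randomness derives from `seed` (data, weight init, training
#' shuffle/dropout, PSO use distinct offsets of it).
#'
#' @param seed Integer master seed.
#' @param epochs Training epochs.
#' @param n_train,n_validation,n_test Images per class and split.
#' @param image_size Image side in pixels (multiple of 32).
#' @param n_classes Number of classes.
#' @param channels Backbone channel widths.
#' @param pso_iterations,pso_particles PSO budget for the fusion stage.
#' @param verbose Print epoch progress.
#' @return List with `trained` (train_cascade result), `untrained_model`,
#'   `weights` (PSO fusion weights), `pso` (full optimiser result),
#'   `test_eval`, `untrained_test_eval`, `ablation`, `data_spec`, and the
#'   headline scalars `test_accuracy`, `untrained_accuracy`.
#' @export
run_desk_experiment <- function(seed = 1L, epochs = 15,
                                n_train = 200, n_validation = 100,
                                n_test = 35, image_size = 64,
                                n_classes = 4,
                                channels = c(8, 16, 32, 64, 64),
                                pso_iterations = 100, pso_particles = 30,
                                verbose = FALSE) {
  spec <- scene_spec(image_size = image_size, n_classes = n_classes,
                     seed = seed)
  data <- generate_dataset(spec, n_train, n_validation, n_test)

  cfg <- backbone_config(input_size = image_size, channels = channels,
                         n_classes = n_classes)
  model0 <- init_cascade(cfg, seed = seed + 1L)
  untrained_test <- evaluate_model(model0, data$test)

  tcfg <- train_config(max_epochs = epochs, seed = seed + 2L)
  trained <- train_cascade(model0, data, tcfg, verbose = verbose)

  val_probs <- collect_pool_probs(trained$model, data$validation)
  pso <- optimize_weights(val_probs$pool_probs, val_probs$labels,
                          swarm_config(n_particles = pso_particles,
                                       n_iterations = pso_iterations,
                                       seed = seed + 3L))
  test_eval <- evaluate_model(trained$model, data$test,
                              fusion_weights = pso$weights)
  ablation <- ablate_scales(trained$model, data$test)

  list(trained = trained, untrained_model = model0, weights = pso$weights,
       pso = pso, test_eval = test_eval,
       untrained_test_eval = untrained_test, ablation = ablation,
       data_spec = spec, data = data,
       test_accuracy = test_eval$report$Acc,
       untrained_accuracy = untrained_test$report$Acc)
}

#' PSO sphere self-test
#'
#' Runs the swarm on the negated 5-D sphere function
#' `-sum((x - 0.3)^2)` whose optimum is known exactly; returns the final
#' distance to the optimum per seed.
#'
#' @param seeds Integer vector of seeds.
#' @param n_iterations,n_particles Swarm budget.
#' @return Numeric vector of Euclidean distances to `(0.3, ..., 0.3)`.
#' @export
pso_sphere_benchmark <- function(seeds = 1:10, n_iterations = 200,
                                 n_particles = 30) {
  vapply(seeds, function(s) {
    res <- optimize_weights(
      cfg = swarm_config(n_particles = n_particles,
                         n_iterations = n_iterations, seed = s),
      dim = 5, fitness_fn = function(x) -sum((x - 0.3)^2))
    sqrt(sum((res$raw_best - 0.3)^2))
  }, numeric(1))
}

#' Synthetic fusion bench
#'
#' Builds the five-head prediction bench used to audit the fusion stage:
#' one informative head that predicts the true class with probability
#' `p_informative` (mass `1 - p_informative` spread over the other
#' classes) and four heads emitting random simplex noise.
#'
#' @param n_samples Number of samples.
#' @param n_classes Number of classes.
#' @param p_informative True-class probability of the informative head.
#' @param informative_head Index (1..5) of the informative head.
#' @param seed Integer seed.
#' @return List with `pool_probs` (5 matrices) and `labels`.
#' @export
fusion_bench <- function(n_samples = 500, n_classes = 4,
                         p_informative = 0.9, informative_head = 5,
                         seed = 1L) {
  set.seed(seed)
  labels <- sample.int(n_classes, n_samples, replace = TRUE) - 1L
  pool <- lapply(1:5, function(k) {
    if (k == informative_head) {
      P <- matrix((1 - p_informative) / (n_classes - 1), n_samples,
                  n_classes)
      # with probability p the head is right; otherwise it votes for a
      # random wrong class
      for (i in seq_len(n_samples)) {
        pick <- if (runif(1) < p_informative) labels[i] else
          sample(setdiff(0:(n_classes - 1), labels[i]), 1)
        P[i, ] <- (1 - p_informative) / (n_classes - 1)
        P[i, pick + 1] <- p_informative
      }
      P
    } else {
      raw <- matrix(rexp(n_samples * n_classes), n_samples, n_classes)
      raw / rowSums(raw)
    }
  })
  list(pool_probs = pool, labels = labels)
}

#' @importFrom stats rexp
NULL
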