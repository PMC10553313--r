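#' Particle swarm configuration
#'
#' Adaptive-inertia PSO over the 5-vector of raw fusion weights. The
#' inertia coefficient is interpolated between `omega_min` and `omega_max`
#' by the fraction of particles that improved in the previous iteration.
#'
#' @param n_particles Swarm size.
#' @param n_iterations Iterations of the main loop.
#' @param cognitive_coeff,social_coeff Attraction coefficients toward the
#'   personal and global best (both default 2).
#' @param omega_max,omega_min Inertia bounds (defaults 1.0 and 0.3).
#' @param velocity_clamp Componentwise velocity bound.
#' @param position_bounds Length-2 interval applied to every dimension,
#'   with reflecting boundaries.
#' @param seed Integer seed.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 30, n_iterations = 100,
                         cognitive_coeff = 2, social_coeff = 2,
                         omega_max = 1.0, omega_min = 0.3,
                         velocity_clamp = 0.5, position_bounds = c(0, 1),
                         seed = 1L) {
  stopifnot(n_particles >= 1, n_iterations >= 1, cognitive_coeff >= 0,
            social_coeff >= 0, omega_min < omega_max, velocity_clamp > 0,
            length(position_bounds) == 2,
            position_bounds[1] < position_bounds[2])
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 cognitive_coeff = cognitive_coeff,
                 social_coeff = social_coeff, omega_max = omega_max,
                 omega_min = omega_min, velocity_clamp = velocity_clamp,
                 position_bounds = position_bounds, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Velocity update rule
#'
#' `v <- omega * v + M r1 (x_ibest - x) + L r2 (x_best - x)`, then clamped
#' componentwise to `[-velocity_clamp, velocity_clamp]`.
#'
#' @param particle List with `x`, `v`, `x_ibest`.
#' @param x_best Global best position.
#' @param omega Inertia coefficient.
#' @param cfg A [swarm_config()].
#' @param r1,r2 Uniform random draws in `[0, 1]`.
#' @return New velocity vector.
#' @export
velocity_update <- function(particle, x_best, omega, cfg, r1, r2) {
  stopifnot(r1 >= 0, r1 <= 1, r2 >= 0, r2 <= 1)
  v <- omega * particle$v +
    cfg$cognitive_coeff * r1 * (particle$x_ibest - particle$x) +
    cfg$social_coeff * r2 * (x_best - particle$x)
  pmin(pmax(v, -cfg$velocity_clamp), cfg$velocity_clamp)
}

#' Position update rule
#'
#' `x <- x + v`, reflected back into `position_bounds`.
#'
#' @param particle List with `x` and (already updated) `v`.
#' @param cfg A [swarm_config()].
#' @return New position vector.
#' @export
position_update <- function(particle, cfg) {
  lo <- cfg$position_bounds[1]; hi <- cfg$position_bounds[2]
  x <- particle$x + particle$v
  # reflect at the walls; in-bounds positions pass through unchanged
  while (any(x < lo | x > hi)) {
    x <- ifelse(x > hi, 2 * hi - x, x)
    x <- ifelse(x < lo, 2 * lo - x, x)
  }
  x
}

#' Adaptive inertia weight
#'
#' `omega = (omega_max - omega_min) * Ps + omega_min`: the inertia grows
#' linearly with the fraction `Ps` of particles that improved last
#' iteration (exploration while the swarm is making progress, contraction
#' once it stalls).
#'
#' @param ps Improvement fraction in `[0, 1]`.
#' @param omega_max,omega_min Inertia bounds.
#' @return Scalar in `[omega_min, omega_max]`.
#' @export
adaptive_inertia <- function(ps, omega_max = 1.0, omega_min = 0.3) {
  if (!is.finite(ps) || ps < 0 || ps > 1)
    stop("improvement fraction must lie in [0, 1]")
  (omega_max - omega_min) * ps + omega_min
}

#' Fraction of strictly improved particles
#'
#' @param fitness_now,fitness_prev Equal-length fitness vectors
#'   (maximisation convention).
#' @return Scalar in `[0, 1]`.
#' @export
improvement_fraction <- function(fitness_now, fitness_prev) {
  if (!length(fitness_now)) stop("empty swarm")
  stopifnot(length(fitness_now) == length(fitness_prev))
  mean(fitness_now > fitness_prev)
}

# Raw weights -> simplex: clip negatives at zero, renormalise; all-zero
# falls back to uniform.
normalize_weights <- function(raw) {
  w <- pmax(raw, 0)
  s <- sum(w)
  if (s <= 0) {
    warning("all-zero clipped weights; falling back to uniform")
    return(rep(1 / length(raw), length(raw)))
  }
  w / s
}

#' Fusion fitness of a raw weight vector
#'
#' Normalises the raw weights to the simplex (clipping negatives), forms
#' the weighted soft vote of the five per-head probability matrices for
#' every sample, takes arg-max labels and returns the accuracy.
#'
#' @param raw_weights Length-5 numeric vector.
#' @param pool_probs List of 5 `n x C` probability matrices (P1..P5 per
#'   sample).
#' @param labels 0-based true labels, length `n`.
#' @return Accuracy in `[0, 1]`.
#' @export
fusion_fitness <- function(raw_weights, pool_probs, labels) {
  w <- normalize_weights(raw_weights)
  P <- pool_prob_cube(pool_probs)
  as.numeric(cpp_fuse_grid_accuracy(P, as.integer(labels),
                                    matrix(w, 1, length(w))))
}

pool_prob_cube <- function(pool_probs) {
  n <- nrow(pool_probs[[1]]); C <- ncol(pool_probs[[1]])
  P <- array(0, c(n, C, length(pool_probs)))
  for (k in seq_along(pool_probs)) P[, , k] <- pool_probs[[k]]
  P
}

#' Optimise fusion weights by adaptive-inertia PSO
#'
#' Positions start uniform in the bounds and velocities at zero. Each
#' iteration evaluates fitness, updates personal and global bests, the
#' improvement fraction `Ps` (defined as 1 on the first iteration, so the
#' inertia starts at `omega_max`), the inertia, then velocities and
#' positions. Reproducible given `cfg$seed`.
#'
#' @param pool_probs List of 5 `n x C` matrices (or `fitness_fn` below).
#' @param labels 0-based true labels.
#' @param cfg A [swarm_config()].
#' @param dim Search dimension (5 for fusion weights).
#' @param fitness_fn Optional custom fitness (maximised) taking a raw
#'   position vector; overrides the fusion fitness. Used by the sphere
#'   self-test.
#' @return List with `weights` (normalised global best, a
#'   `fusion_weights` vector), `raw_best`, `best_fitness`, and `trace`
#'   (data.frame per iteration: best fitness, Ps, omega).
#' @export
optimize_weights <- function(pool_probs = NULL, labels = NULL,
                             cfg = swarm_config(), dim = 5,
                             fitness_fn = NULL) {
  if (is.null(fitness_fn)) {
    if (is.null(pool_probs) || is.null(labels) || !nrow(pool_probs[[1]]))
      stop("nonempty pool_probs and labels are required")
    P <- pool_prob_cube(pool_probs)
    labs <- as.integer(labels)
    fitness_fn <- function(x)
      as.numeric(cpp_fuse_grid_accuracy(P, labs,
                                        matrix(normalize_weights(x), 1)))
  }
  set.seed(cfg$seed)
  lo <- cfg$position_bounds[1]; hi <- cfg$position_bounds[2]
  n <- cfg$n_particles
  X <- matrix(runif(n * dim, lo, hi), n, dim)
  V <- matrix(0, n, dim)
  fit <- apply(X, 1, fitness_fn)
  pbest <- X; pbest_fit <- fit
  gi <- which.max(fit)
  gbest <- X[gi, ]; gbest_fit <- fit[gi]
  trace <- data.frame(iteration = 0L, best_fitness = gbest_fit,
                      ps = NA_real_, omega = NA_real_)
  fit_prev <- fit
  for (it in seq_len(cfg$n_iterations)) {
    ps <- if (it == 1) 1 else improvement_fraction(fit, fit_prev)
    omega <- adaptive_inertia(ps, cfg$omega_max, cfg$omega_min)
    fit_prev <- fit
    for (p in seq_len(n)) {
      r1 <- runif(1); r2 <- runif(1)
      part <- list(x = X[p, ], v = V[p, ], x_ibest = pbest[p, ])
      V[p, ] <- velocity_update(part, gbest, omega, cfg, r1, r2)
      part$v <- V[p, ]
      X[p, ] <- position_update(part, cfg)
    }
    fit <- apply(X, 1, fitness_fn)
    improved <- fit > pbest_fit
    pbest[improved, ] <- X[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    gi <- which.max(pbest_fit)
    if (pbest_fit[gi] > gbest_fit) {
      gbest_fit <- pbest_fit[gi]
      gbest <- pbest[gi, ]
    }
    trace <- rbind(trace, data.frame(iteration = it,
                                     best_fitness = gbest_fit, ps = ps,
                                     omega = omega))
  }
  list(weights = normalize_weights(gbest), raw_best = gbest,
       best_fitness = gbest_fit, trace = trace)
}

#' Final fused prediction
#'
#' Weighted soft vote of P1..P5 under convex fusion weights; arg-max with
#' lowest-index tie-breaking.
#'
#' @param pool_probs List of 5 class-probability vectors.
#' @param weights Length-5 convex weights.
#' @return List with `label` (0-based) and `prob` (fused vector).
#' @export
final_predict <- function(pool_probs, weights) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("fusion weights must be convex")
  fused <- soft_vote(pool_probs, weights)
  list(label = which.max(fused) - 1L, prob = fused)
}

#' Exhaustive simplex grid search over fusion weights
#'
#' Evaluates fused accuracy at every weight vector on the simplex grid
#' with the given step; the optimiser-independent oracle used to audit
#' [optimize_weights()].
#'
#' @param pool_probs List of 5 `n x C` matrices.
#' @param labels 0-based labels.
#' @param step Grid step (default 0.05).
#' @return List with `best_fitness`, `best_weights`, `n_points`.
#' @export
grid_search_weights <- function(pool_probs, labels, step = 0.05) {
  K <- length(pool_probs)
  units <- round(1 / step)
  combos <- compositions(units, K)
  Wgrid <- combos / units
  acc <- cpp_fuse_grid_accuracy(pool_prob_cube(pool_probs),
                                as.integer(labels), Wgrid)
  i <- which.max(acc)
  list(best_fitness = acc[i], best_weights = Wgrid[i, ],
       n_points = nrow(Wgrid))
}

# All K-part compositions of n (rows sum to n).
compositions <- function(n, K) {
  if (K == 1) return(matrix(n, 1, 1))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, K - 1)
    out[[first + 1]] <- cbind(first, rest)
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}
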