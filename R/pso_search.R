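# Stage 2: binary particle swarm search over the filtered gene pool.
# Positions are bit vectors (1 = gene included); velocities are real and
# mapped through a sigmoid to per-bit inclusion probabilities. The fitness
# f(x) = alpha * Error(x) + beta * |x| / D is MINIMIZED: strict-improvement
# elitism on personal and global bests makes the global-best trace
# non-increasing.

#' Configuration for the binary particle swarm optimizer
#'
#' Defaults follow common binary-PSO practice: high inertia (in the binary
#' variant a low inertia weight lets velocities decay to the sigmoid's
#' 50% noise floor and the swarm never settles, so w = 0.9 rather than the
#' 0.7 typical of real-valued PSO), the classic symmetric accelerations
#' c1 = c2 = 2, velocity clamp at 6 (sigmoid(6) ~ 0.998, so a bit is never
#' frozen), and sparse initialization biased toward small subsets.
#'
#' @param n_particles Swarm size (>= 2, default 30).
#' @param max_iter Maximum iterations (default 100).
#' @param w Inertia weight (default 0.9).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2
#'   each).
#' @param v_max Component-wise velocity clamp (default 6).
#' @param stall_iters Stop after this many iterations without global-best
#'   improvement (default 20).
#' @param init_prob Probability a bit starts set at initialization
#'   (default 0.1).
#' @param seed Integer seed; the whole run is a pure function of its inputs
#'   and this seed.
#' @return An object of class `PSOConfig`.
#' @export
pso_config <- function(n_particles = 30L, max_iter = 100L, w = 0.9,
                       c1 = 2, c2 = 2, v_max = 6, stall_iters = 20L,
                       init_prob = 0.1, seed = 1L) {
  n_particles <- as.integer(n_particles); max_iter <- as.integer(max_iter)
  if (n_particles < 2L) stop("n_particles must be >= 2")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (v_max <= 0) stop("v_max must be > 0")
  if (c1 < 0 || c2 < 0) stop("c1 and c2 must be >= 0")
  if (init_prob <= 0 || init_prob > 1) stop("init_prob must be in (0, 1]")
  structure(list(n_particles = n_particles, max_iter = max_iter, w = w,
                 c1 = c1, c2 = c2, v_max = v_max,
                 stall_iters = as.integer(stall_iters),
                 init_prob = init_prob, seed = as.integer(seed)),
            class = "PSOConfig")
}

#' Configuration of the subset fitness f(x) = alpha Error(x) + beta |x| / D
#'
#' `Error(x)` is the cross-validated misclassification rate of the wrapped
#' classifier on the genes whose bits are set; `|x|/D` is the relative
#' subset size over the D candidate genes. During the search the error is
#' estimated by stratified k-fold cross-validation by default (leave-one-out
#' per particle per iteration is quadratically expensive); leave-one-out is
#' available via `error_estimator = "loocv"` and is always used for final
#' reporting.
#'
#' @param alpha Weight on classification error (default 0.9).
#' @param beta Weight on relative subset size (default 0.1);
#'   `alpha + beta` must be > 0.
#' @param error_estimator `"kfold"` (default) or `"loocv"`.
#' @param k_folds Folds for the k-fold estimator (default 5).
#' @param classifier A [classifier_config()].
#' @return An object of class `FitnessConfig`.
#' @export
fitness_config <- function(alpha = 0.9, beta = 0.1,
                           error_estimator = c("kfold", "loocv"),
                           k_folds = 5L, classifier = classifier_config()) {
  error_estimator <- match.arg(error_estimator)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (alpha + beta <= 0) stop("alpha + beta must be > 0")
  structure(list(alpha = alpha, beta = beta,
                 error_estimator = error_estimator,
                 k_folds = as.integer(k_folds), classifier = classifier),
            class = "FitnessConfig")
}

#' Fitness of a candidate gene-inclusion bit vector
#'
#' @param position Binary (0/1) vector over the pool, at least one bit set.
#' @param pool `GeneSubset` of candidate genes; `length(position)` must
#'   equal the pool size.
#' @param dataset An [expression_dataset()].
#' @param cfg A [fitness_config()].
#' @param cv_seed Seed for the cross-validation fold shuffle (held fixed
#'   across a swarm run so fitness values are comparable).
#' @return `alpha * Error + beta * sum(position) / D`, lower is better.
#' @export
subset_fitness <- function(position, pool, dataset, cfg = fitness_config(),
                           cv_seed = 1L) {
  if (length(position) != length(pool$gene_ids))
    stop("position length != pool size")
  on <- position != 0
  if (!any(on)) stop("all-zero position must be repaired before evaluation")
  D <- length(position)
  err <- if (cfg$alpha == 0) {
    0 # size-only fitness: skip the classifier entirely
  } else {
    sub <- gene_subset(pool$gene_ids[on], "pso")
    switch(cfg$error_estimator,
           kfold = cv_error(dataset, sub, cfg$classifier, cfg$k_folds, cv_seed),
           loocv = 1 - loocv_accuracy(dataset, sub, cfg$classifier)$accuracy)
  }
  cfg$alpha * err + cfg$beta * sum(on) / D
}

#' Velocity update for one particle
#'
#' v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x), with r1 and r2 fresh
#' uniform(0,1) draws per component from the current RNG stream, clamped
#' component-wise to `[-v_max, v_max]`.
#'
#' @param velocity,position,best_position Numeric vectors of equal length
#'   (position and best_position are 0/1).
#' @param global_best Swarm-best 0/1 vector.
#' @param cfg A [pso_config()].
#' @return Clamped velocity vector.
#' @export
update_velocity <- function(velocity, position, best_position, global_best,
                            cfg) {
  d <- length(velocity)
  stopifnot(length(position) == d, length(best_position) == d,
            length(global_best) == d)
  v <- cfg$w * velocity +
    cfg$c1 * stats::runif(d) * (best_position - position) +
    cfg$c2 * stats::runif(d) * (global_best - position)
  pmin(pmax(v, -cfg$v_max), cfg$v_max)
}

#' Stochastic position update through the sigmoid transfer function
#'
#' Each bit is set independently with probability sigmoid(v) =
#' 1/(1+exp(-v)); an all-zero outcome is repaired by switching one
#' uniformly chosen bit on (an empty gene set has no defined classifier
#' error).
#'
#' @param velocity Clamped velocity vector.
#' @return Integer 0/1 vector with at least one bit set.
#' @export
update_position <- function(velocity) {
  prob <- 1 / (1 + exp(-velocity))
  bits <- as.integer(stats::runif(length(velocity)) < prob)
  repair_position(bits)
}

# Guarantee at least one set bit (uniform choice uses the RNG stream, so
# repair is reproducible under the run seed).
repair_position <- function(bits) {
  if (!any(bits == 1L)) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}

#' Personal-best and global-best bookkeeping
#'
#' Replaces the particle's best iff the new fitness is strictly smaller,
#' and likewise the swarm's global best; ties keep the incumbent.
#'
#' @param particle List with `position`, `best_position`, `best_fitness`.
#' @param swarm List with `global_best_position`, `global_best_fitness`.
#' @param fit Fitness of `particle$position`.
#' @return List `(particle, swarm)` with updated bests.
#' @export
update_bests <- function(particle, swarm, fit) {
  if (fit < particle$best_fitness) {
    particle$best_position <- particle$position
    particle$best_fitness <- fit
  }
  if (fit < swarm$global_best_fitness) {
    swarm$global_best_position <- particle$position
    swarm$global_best_fitness <- fit
  }
  list(particle = particle, swarm = swarm)
}

#' Run the binary particle swarm over an arbitrary fitness function
#'
#' Core loop: initialize -> evaluate -> update bests -> update velocity and
#' position, until `max_iter` iterations or `stall_iters` without
#' global-best improvement. Identical fitness values are cached by bit
#' pattern (particles revisit subsets; caching changes no result, only
#' runtime).
#'
#' @param fitness_fn Function taking a 0/1 vector of length `d` and
#'   returning a scalar fitness (lower is better).
#' @param d Search-space dimension.
#' @param cfg A [pso_config()].
#' @return List with `best_position` (0/1 vector), `best_fitness`, `trace`
#'   (global best fitness after each iteration, non-increasing) and
#'   `iterations` (number executed).
#' @export
pso_optimize <- function(fitness_fn, d, cfg = pso_config()) {
  if (d < 1L) stop("search dimension must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  eval_fit <- function(bits) {
    key <- paste(which(bits == 1L), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- fitness_fn(bits)
    cache[[key]] <- val
    val
  }

  particles <- lapply(seq_len(cfg$n_particles), function(i) {
    pos <- repair_position(as.integer(stats::runif(d) < cfg$init_prob))
    list(position = pos,
         velocity = stats::runif(d, -1, 1),
         best_position = pos,
         best_fitness = Inf)
  })
  swarm <- list(global_best_position = particles[[1L]]$position,
                global_best_fitness = Inf)

  trace <- numeric(0)
  stall <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    prev_best <- swarm$global_best_fitness
    for (i in seq_along(particles)) {
      fit <- eval_fit(particles[[i]]$position)
      upd <- update_bests(particles[[i]], swarm, fit)
      particles[[i]] <- upd$particle
      swarm <- upd$swarm
    }
    trace <- c(trace, swarm$global_best_fitness)
    stall <- if (swarm$global_best_fitness < prev_best) 0L else stall + 1L
    if (iter == cfg$max_iter || stall >= cfg$stall_iters) break
    for (i in seq_along(particles)) {
      v <- update_velocity(particles[[i]]$velocity, particles[[i]]$position,
                           particles[[i]]$best_position,
                           swarm$global_best_position, cfg)
      particles[[i]]$velocity <- v
      particles[[i]]$position <- update_position(v)
    }
  }
  list(best_position = swarm$global_best_position,
       best_fitness = swarm$global_best_fitness,
       trace = trace, iterations = length(trace))
}

#' Select a gene subset from a filtered pool by binary PSO
#'
#' Wraps [pso_optimize()] with the subset fitness of [subset_fitness()] and
#' maps the best bit vector back to gene identifiers in pool order.
#'
#' @param pool `GeneSubset` of candidate genes (the filter's kept pool).
#' @param dataset An [expression_dataset()].
#' @param pso_cfg A [pso_config()].
#' @param fit_cfg A [fitness_config()].
#' @return List with `subset` (a `GeneSubset` tagged `"pso"`), `fitness`,
#'   `trace` and `iterations`.
#' @export
optimize_subset <- function(pool, dataset, pso_cfg = pso_config(),
                            fit_cfg = fitness_config()) {
  stopifnot(inherits(pool, "GeneSubset"))
  d <- length(pool$gene_ids)
  if (d == 0L) stop("candidate pool is empty")
  fitness_fn <- function(bits)
    subset_fitness(bits, pool, dataset, fit_cfg, cv_seed = pso_cfg$seed)
  res <- pso_optimize(fitness_fn, d, pso_cfg)
  list(subset = gene_subset(pool$gene_ids[res$best_position == 1L], "pso"),
       fitness = res$best_fitness, trace = res$trace,
       iterations = res$iterations)
}
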