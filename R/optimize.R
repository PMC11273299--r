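#' Hyperparameter search space for the boosted-tree classifier
#'
#' Seven tunable dimensions of the extreme-gradient-boosting model. Each
#' dimension has finite bounds, a type (`"real"` or `"int"`, integers rounded
#' half-up on decode) and a scale (`"linear"` or `"log"`; the learning rate
#' is searched log-uniformly).
#'
#' @param learning_rate,n_estimators,max_depth,min_child_weight,gamma,subsample,colsample_bytree
#'   Length-2 numeric bounds `c(lower, upper)` per dimension.
#' @return Object of class `hyperparam_space`: a data frame with columns
#'   name, lower, upper, type, scale.
#' @export
hyperparam_space <- function(learning_rate = c(0.01, 0.3),
                             n_estimators = c(50, 500),
                             max_depth = c(3, 10),
                             min_child_weight = c(1, 10),
                             gamma = c(0, 5),
                             subsample = c(0.5, 1.0),
                             colsample_bytree = c(0.5, 1.0)) {
  dims <- list(learning_rate = learning_rate, n_estimators = n_estimators,
               max_depth = max_depth, min_child_weight = min_child_weight,
               gamma = gamma, subsample = subsample,
               colsample_bytree = colsample_bytree)
  for (nm in names(dims)) {
    b <- dims[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2]) {
      stop("invalid bounds for ", nm)
    }
  }
  space <- data.frame(
    name = names(dims),
    lower = vapply(dims, `[`, numeric(1), 1),
    upper = vapply(dims, `[`, numeric(1), 2),
    type = c("real", "int", "int", "real", "real", "real", "real"),
    scale = c("log", "linear", "linear", "linear", "linear", "linear",
              "linear"),
    stringsAsFactors = FALSE)
  class(space) <- c("hyperparam_space", "data.frame")
  space
}

round_half_up <- function(x) floor(x + 0.5)

#' Decode a normalized chromosome into hyperparameters
#'
#' Genes live in \[0, 1\]; out-of-range genes are clipped with a warning.
#' Linear dimensions map affinely into their bounds, log dimensions
#' log-affinely, and integer dimensions are rounded half-up.
#'
#' @param genes Numeric vector, one gene per space dimension.
#' @param space A [hyperparam_space()].
#' @return Named list of decoded hyperparameter values.
#' @export
decode_chromosome <- function(genes, space = hyperparam_space()) {
  if (length(genes) != nrow(space)) {
    stop("chromosome has ", length(genes), " genes; space has ", nrow(space),
         " dimensions")
  }
  if (any(genes < 0 | genes > 1)) {
    warning("genes outside [0, 1] clipped")
    genes <- pmin(pmax(genes, 0), 1)
  }
  out <- vector("list", nrow(space))
  names(out) <- space$name
  for (i in seq_len(nrow(space))) {
    lo <- space$lower[i]; hi <- space$upper[i]
    v <- if (space$scale[i] == "log") {
      exp(log(lo) + genes[i] * (log(hi) - log(lo)))
    } else {
      lo + genes[i] * (hi - lo)
    }
    if (space$type[i] == "int") v <- round_half_up(v)
    out[[i]] <- v
  }
  out
}

encode_point <- function(point, space) {
  vapply(seq_len(nrow(space)), function(i) {
    lo <- space$lower[i]; hi <- space$upper[i]; v <- point[[space$name[i]]]
    if (space$scale[i] == "log") {
      (log(v) - log(lo)) / (log(hi) - log(lo))
    } else {
      (v - lo) / (hi - lo)
    }
  }, numeric(1))
}

#' Cross-validated fitness function for hyperparameter optimization
#'
#' Builds the objective maximized by the optimizers: the mean stratified
#' k-fold CV accuracy of the boosted-tree classifier at a decoded
#' chromosome. Evaluations are memoized per decoded point within the run
#' (memoization never changes values, only skips recomputation) and a
#' training failure scores 0.
#'
#' @param X Feature matrix (canonically the fused 106-feature matrix).
#' @param y Binary labels.
#' @param space A [hyperparam_space()].
#' @param k CV folds.
#' @param seed Integer seed (folds and fits).
#' @return Function `f(genes) -> fitness in [0, 1]`, with attributes
#'   `n_evaluations()` and `n_unique()` accessors.
#' @export
xgb_cv_fitness <- function(X, y, space = hyperparam_space(), k = 10L,
                           seed = 1L) {
  memo <- new.env(parent = emptyenv())
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  f <- function(genes) {
    calls$n <- calls$n + 1L
    hp <- decode_chromosome(genes, space)
    key <- paste(sprintf("%.12g", unlist(hp)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- tryCatch({
      cv <- stratified_cv(classifier_spec("xgboost", hp), X, y, k = k,
                          seed = seed)
      cv$metrics$accuracy
    }, error = function(e) {
      warning("fitness evaluation failed (", conditionMessage(e),
              "); scored 0")
      0
    })
    memo[[key]] <- val
    val
  }
  attr(f, "n_evaluations") <- function() calls$n
  attr(f, "n_unique") <- function() length(ls(memo))
  f
}

#' Genetic-algorithm configuration
#'
#' @param population_size Initial population size (default 100).
#' @param refined_size Population size after teaching-learning refinement
#'   (TLBPSGA only; default half the population, e.g. 100 -> 50).
#' @param generations Generational budget (default 100).
#' @param r_min,r_max Crossover-probability schedule bounds (defaults
#'   0.6/0.95); see [crossover_rate()].
#' @param mutation_rate Per-gene uniform mutation probability (default 0.1).
#' @param tournament_k Tournament size for parent selection (default 3).
#' @param elitism Number of elite individuals copied unchanged (default 1).
#' @param stagnation_window Stop early after this many generations without
#'   improvement (TLBPSGA; default 25).
#' @param refine_each_generation Run one teaching-learning pass per
#'   generation (default `TRUE`; `FALSE` refines only the initial
#'   population).
#' @param seed Integer seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, refined_size = NULL,
                      generations = 100L, r_min = 0.6, r_max = 0.95,
                      mutation_rate = 0.1, tournament_k = 3L, elitism = 1L,
                      stagnation_window = 25L, refine_each_generation = TRUE,
                      seed = 1L) {
  if (is.null(refined_size)) {
    refined_size <- max(2L, as.integer(population_size) %/% 2L)
  }
  if (refined_size > population_size) {
    stop("refined_size must not exceed population_size")
  }
  if (mutation_rate < 0 || mutation_rate > 1 ||
      r_min < 0 || r_max > 1 || r_min > r_max) {
    stop("rates must lie in [0, 1] with r_min <= r_max")
  }
  cfg <- list(population_size = as.integer(population_size),
              refined_size = as.integer(refined_size),
              generations = as.integer(generations),
              r_min = r_min, r_max = r_max, mutation_rate = mutation_rate,
              tournament_k = as.integer(tournament_k),
              elitism = as.integer(elitism),
              stagnation_window = as.integer(stagnation_window),
              refine_each_generation = isTRUE(refine_each_generation),
              seed = as.integer(seed))
  class(cfg) <- "ga_config"
  cfg
}

#' Generation-dependent crossover probability
#'
#' The crossover probability rises linearly with the generation count:
#' R(g) = r_min + (r_max - r_min) g / G. A low early rate preserves good
#' schemata while the population is diverse; the rate grows as individuals
#' converge.
#'
#' @param g Current generation, `0 <= g <= G`.
#' @param config A [ga_config()].
#' @return Crossover probability.
#' @export
crossover_rate <- function(g, config) {
  G <- config$generations
  if (g < 0 || g > G) stop("generation out of range")
  config$r_min + (config$r_max - config$r_min) * g / G
}

#' Tournament selection
#'
#' Samples `k` distinct individuals and returns the index of the fittest.
#'
#' @param fitnesses Fitness vector of the population.
#' @param k Tournament size (`k <=` population size).
#' @return Index of the selected parent.
#' @export
tournament_select <- function(fitnesses, k = 3L) {
  n <- length(fitnesses)
  if (k > n) stop("tournament size exceeds population")
  idx <- sample.int(n, k)
  idx[which.max(fitnesses[idx])]
}

# Fitness-proportional (roulette) selection; fitness shifted to be positive.
roulette_select <- function(fitnesses) {
  w <- fitnesses - min(fitnesses) + 1e-12
  sample.int(length(fitnesses), 1, prob = w)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Single-point crossover of two gene vectors: point in 1..(len-1), children
# swap tails after the point.
single_point_crossover <- function(a, b, point = NULL) {
  len <- length(a)
  if (is.null(point)) point <- sample.int(len - 1L, 1)
  c1 <- c(a[seq_len(point)], b[(point + 1L):len])
  c2 <- c(b[seq_len(point)], a[(point + 1L):len])
  list(c1, c2)
}

mutate_genes <- function(genes, rate) {
  hit <- stats::runif(length(genes)) < rate
  if (any(hit)) genes[hit] <- stats::runif(sum(hit))
  genes
}

# First generation (0 = initial population) at which the best-so-far came
# within `tol` of the run's final best fitness. The tolerance absorbs the
# vanishing tail of micro-improvements a continuous objective produces;
# 1e-4 is one decade finer than fitness scores are conventionally reported.
first_attainment <- function(trajectory, best_fitness, tol = 1e-4) {
  which(trajectory >= best_fitness - tol)[1] - 1L
}

ga_result <- function(best_genes, best_fitness, trajectory, first_attained,
                      n_evaluations, space, method) {
  out <- list(best_genes = best_genes,
              best_params = decode_chromosome(best_genes, space),
              best_fitness = best_fitness, trajectory = trajectory,
              first_attained = first_attained,
              n_evaluations = n_evaluations, method = method)
  class(out) <- "ga_result"
  out
}

#' @export
print.ga_result <- function(x, ...) {
  cat(x$method, "result: best fitness", sprintf("%.4f", x$best_fitness),
      "first attained at generation", x$first_attained, "\n")
  cat("evaluations:", x$n_evaluations, "\n")
  invisible(x)
}

#' Exhaustive grid search
#'
#' Evaluates the full Cartesian product of per-dimension gene grids (values
#' equally spaced in \[0, 1\], endpoints included) and returns the argmax;
#' ties resolve to the first cell in lexicographic order.
#'
#' @param space A [hyperparam_space()].
#' @param grid_sizes Integer number of values per dimension (scalar or one
#'   per dimension).
#' @param fitness Fitness function over normalized genes.
#' @param budget Maximum number of cells allowed (default 20000).
#' @return A `ga_result` (trajectory = running best over evaluation order).
#' @export
grid_search <- function(space, grid_sizes, fitness, budget = 20000L) {
  d <- nrow(space)
  grid_sizes <- rep_len(as.integer(grid_sizes), d)
  n_cells <- prod(grid_sizes)
  if (n_cells > budget) {
    stop("grid has ", n_cells, " cells, exceeding the budget of ", budget)
  }
  axes <- lapply(grid_sizes, function(gi) {
    if (gi == 1L) 0.5 else seq(0, 1, length.out = gi)
  })
  # lexicographic order: last dimension varies slowest
  grid <- as.matrix(expand.grid(rev(axes)))[, d:1, drop = FALSE]
  best_fit <- -Inf; best_genes <- NULL; best_at <- NA_integer_
  traj <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    v <- fitness(grid[i, ])
    if (v > best_fit) {
      best_fit <- v; best_genes <- grid[i, ]; best_at <- i
    }
    traj[i] <- best_fit
  }
  ga_result(best_genes, best_fit, traj, best_at, n_cells, space,
            "grid_search")
}

#' Classical genetic algorithm
#'
#' Random initial population; fitness-proportional parent selection;
#' single-point crossover applied with the generation-dependent probability
#' [crossover_rate()]; per-gene uniform mutation (gene resampled from
#' U\[0, 1\]); elitism carries the best individuals unchanged. Runs for the
#' configured number of generations.
#'
#' @param space A [hyperparam_space()].
#' @param fitness Fitness function over normalized genes (maximized).
#' @param config A [ga_config()].
#' @return A `ga_result`; the trajectory (best-so-far per generation,
#'   generation 0 = initial population) is non-decreasing under elitism.
#' @export
classical_ga <- function(space, fitness, config = ga_config()) {
  set.seed(config$seed)
  d <- nrow(space)
  p <- config$population_size
  pop <- matrix(stats::runif(p * d), p, d)
  fit <- apply(pop, 1, fitness)
  n_eval <- p
  best_idx <- which.max(fit)
  best_fit <- fit[best_idx]; best_genes <- pop[best_idx, ]
  traj <- numeric(config$generations + 1L)
  traj[1] <- best_fit
  for (g in seq_len(config$generations)) {
    R <- crossover_rate(g, config)
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    while (nrow(newpop) < p) {
      pa <- pop[roulette_select(fit), ]
      pb <- pop[roulette_select(fit), ]
      kids <- if (stats::runif(1) < R) single_point_crossover(pa, pb) else
        list(pa, pb)
      kids <- lapply(kids, mutate_genes, rate = config$mutation_rate)
      newpop <- rbind(newpop, kids[[1]], kids[[2]])
    }
    pop <- newpop[seq_len(p), , drop = FALSE]
    fit <- apply(pop, 1, fitness)
    n_eval <- n_eval + p
    gi <- which.max(fit)
    if (fit[gi] > best_fit + 1e-12) {
      best_fit <- fit[gi]; best_genes <- pop[gi, ]
    }
    traj[g + 1L] <- best_fit
  }
  ga_result(best_genes, best_fit, traj, first_attainment(traj, best_fit),
            n_eval, space, "classical_ga")
}

#' One teaching-learning refinement pass
#'
#' Teacher phase: the fittest individual teaches; every learner moves by
#' new = old + rand * (teacher - TF * mean), with the per-gene random factor
#' rand ~ U(0, 1), the teaching factor TF = round(1 + U(0, 1)) in \{1, 2\},
#' and mean the per-gene population mean. Improved solutions replace old
#' ones; a learner surpassing the teacher becomes the teacher. Learner
#' phase: each learner pairs with a random other and moves toward it if the
#' partner is fitter (new = old + rand * (partner - old)), away otherwise
#' (new = old + rand * (old - partner)), accepted on improvement. Finally
#' the fittest `refined_size` individuals are kept.
#'
#' @param pop Population matrix (rows = individuals, genes in \[0, 1\]).
#' @param fit Fitness vector for `pop`.
#' @param fitness Fitness function.
#' @param refined_size Number of individuals to keep.
#' @return List with elements `pop`, `fit` and `n_evaluations`.
#' @export
tlbo_refine <- function(pop, fit, fitness, refined_size = nrow(pop)) {
  n <- nrow(pop); d <- ncol(pop)
  if (n < 2) stop("population must have at least 2 individuals")
  if (refined_size > n) stop("refined_size exceeds population size")
  n_eval <- 0L
  teacher <- which.max(fit)
  # teaching phase
  mean_vec <- colMeans(pop)
  for (i in seq_len(n)) {
    if (i == teacher) next
    tf <- round_half_up(1 + stats::runif(1))
    cand <- clip01(pop[i, ] + stats::runif(d) * (pop[teacher, ] -
                                                   tf * mean_vec))
    cf <- fitness(cand)
    n_eval <- n_eval + 1L
    if (cf > fit[i]) {
      pop[i, ] <- cand
      fit[i] <- cf
      if (cf > fit[teacher]) teacher <- i
    }
  }
  # learner phase
  for (i in seq_len(n)) {
    j <- sample.int(n - 1L, 1)
    if (j >= i) j <- j + 1L
    cand <- if (fit[j] > fit[i]) {
      clip01(pop[i, ] + stats::runif(d) * (pop[j, ] - pop[i, ]))
    } else {
      clip01(pop[i, ] + stats::runif(d) * (pop[i, ] - pop[j, ]))
    }
    cf <- fitness(cand)
    n_eval <- n_eval + 1L
    if (cf > fit[i]) {
      pop[i, ] <- cand
      fit[i] <- cf
    }
  }
  keep <- order(fit, decreasing = TRUE)[seq_len(refined_size)]
  list(pop = pop[keep, , drop = FALSE], fit = fit[keep],
       n_evaluations = n_eval)
}

#' Teaching-learning-based population-selection genetic algorithm
#'
#' A genetic algorithm whose mating population is refined by
#' teaching-learning passes. The random initial population (of
#' `population_size`) is refined down to `refined_size` by [tlbo_refine()];
#' each generation then selects parents by tournament, applies single-point
#' crossover at the [crossover_rate()] schedule and uniform mutation, keeps
#' elites, and (by default) re-refines the population with one
#' teaching-learning pass. Stops at the generation budget or after
#' `stagnation_window` generations without improvement.
#'
#' @inheritParams classical_ga
#' @return A `ga_result` with the convergence trajectory and the generation
#'   at which the final best fitness was first attained.
#' @export
tlbpsga <- function(space, fitness, config = ga_config()) {
  set.seed(config$seed)
  d <- nrow(space)
  p0 <- config$population_size
  pop <- matrix(stats::runif(p0 * d), p0, d)
  fit <- apply(pop, 1, fitness)
  n_eval <- p0
  ref <- tlbo_refine(pop, fit, fitness, config$refined_size)
  pop <- ref$pop; fit <- ref$fit
  n_eval <- n_eval + ref$n_evaluations
  p <- config$refined_size
  best_fit <- max(fit); best_genes <- pop[which.max(fit), ]
  last_improved <- 0L
  traj <- best_fit
  for (g in seq_len(config$generations)) {
    R <- crossover_rate(g, config)
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    while (nrow(newpop) < p) {
      pa <- pop[tournament_select(fit, config$tournament_k), ]
      pb <- pop[tournament_select(fit, config$tournament_k), ]
      kids <- if (stats::runif(1) < R) single_point_crossover(pa, pb) else
        list(pa, pb)
      kids <- lapply(kids, mutate_genes, rate = config$mutation_rate)
      newpop <- rbind(newpop, kids[[1]], kids[[2]])
    }
    pop <- newpop[seq_len(p), , drop = FALSE]
    fit <- apply(pop, 1, fitness)
    n_eval <- n_eval + p
    if (config$refine_each_generation) {
      ref <- tlbo_refine(pop, fit, fitness, p)
      pop <- ref$pop; fit <- ref$fit
      n_eval <- n_eval + ref$n_evaluations
    }
    gi <- which.max(fit)
    if (fit[gi] > best_fit + 1e-12) {
      best_fit <- fit[gi]; best_genes <- pop[gi, ]; last_improved <- g
    }
    traj <- c(traj, best_fit)
    if (g - last_improved >= config$stagnation_window) break
  }
  ga_result(best_genes, best_fit, traj, first_attainment(traj, best_fit),
            n_eval, space, "tlbpsga")
}
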