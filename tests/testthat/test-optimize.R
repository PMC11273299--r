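test_that("chromosome decode maps gene bounds onto parameter bounds", {
  sp <- hyperparam_space()
  lo <- decode_chromosome(rep(0, 7), sp)
  hi <- decode_chromosome(rep(1, 7), sp)
  expect_equal(unlist(lo), stats::setNames(sp$lower, sp$name))
  expect_equal(unlist(hi), stats::setNames(sp$upper, sp$name))

  mid <- decode_chromosome(rep(0.5, 7), sp)
  expect_equal(mid$max_depth, 7)                # round(6.5) half-up
  expect_equal(mid$learning_rate, sqrt(0.01 * 0.3))   # log-scale midpoint
  expect_equal(mid$subsample, 0.75)

  expect_warning(decode_chromosome(c(rep(0.5, 6), 1.2), sp), "clipped")
  expect_error(decode_chromosome(rep(0.5, 6), sp), "dimensions")
  expect_error(hyperparam_space(max_depth = c(10, 3)), "invalid bounds")

  # decode(encode(p)) = p for in-bounds points, up to integer rounding
  p <- list(learning_rate = 0.05, n_estimators = 200, max_depth = 5,
            min_child_weight = 2, gamma = 1, subsample = 0.8,
            colsample_bytree = 0.9)
  genes <- pupasex:::encode_point(p, sp)
  expect_equal(decode_chromosome(genes, sp), p, tolerance = 1e-12)
})

test_that("crossover probability rises linearly across generations", {
  cfg <- ga_config(generations = 100, r_min = 0.6, r_max = 0.95)
  expect_equal(crossover_rate(0, cfg), 0.6)
  expect_equal(crossover_rate(100, cfg), 0.95)
  expect_equal(crossover_rate(50, cfg), 0.775)
  expect_error(crossover_rate(101, cfg), "out of range")
})

test_that("single-point crossover swaps tails at the chosen point", {
  kids <- pupasex:::single_point_crossover(c(1, 2, 3, 4), c(5, 6, 7, 8),
                                           point = 2)
  expect_equal(kids[[1]], c(1, 2, 7, 8))
  expect_equal(kids[[2]], c(5, 6, 3, 4))
})

test_that("grid search is exhaustive, deterministic and budget-capped", {
  sp <- hyperparam_space()
  counter <- local({n <- 0; function(genes) {n <<- n + 1; sphere_fitness(genes)}})
  res <- grid_search(sp, 2L, counter)
  expect_equal(res$n_evaluations, 128)

  # rigged fitness: a unique known-optimal cell is found
  target <- c(0, 1, 0, 1, 0, 1, 0)
  rigged <- function(genes) -sum(abs(genes - target))
  res2 <- grid_search(sp, 2L, rigged)
  expect_equal(unname(res2$best_genes), target)
  res3 <- grid_search(sp, 2L, rigged)
  expect_identical(res2$best_fitness, res3$best_fitness)

  expect_error(grid_search(sp, 5L, sphere_fitness, budget = 100), "78125")
})

test_that("tournament selection returns the fittest of the sampled k", {
  set.seed(1)
  expect_equal(tournament_select(c(0.3, 0.9, 0.1), k = 3), 2L)
  set.seed(2)
  for (r in 1:20) {
    expect_equal(tournament_select(c(0.1, 0.9), k = 2), 2L)
  }
  # selection pressure: the best individual is chosen most often
  set.seed(3)
  fits <- seq(0.1, 1, length.out = 10)
  picks <- replicate(2000, tournament_select(fits, k = 3))
  tab <- tabulate(picks, 10)
  expect_equal(which.max(tab), 10L)
  expect_error(tournament_select(c(1, 2), k = 3), "exceeds")
})

test_that("teaching-learning refinement improves and truncates population", {
  set.seed(11)
  pop <- matrix(runif(20 * 7), 20, 7)
  fit <- apply(pop, 1, sphere_fitness)
  ref <- tlbo_refine(pop, fit, sphere_fitness, refined_size = 10)
  expect_equal(nrow(ref$pop), 10)
  expect_length(ref$fit, 10)
  # greedy acceptance + truncation: refined minimum >= original median
  expect_gte(min(ref$fit), stats::median(fit))
  expect_equal(ref$fit, apply(ref$pop, 1, sphere_fitness))
  expect_true(all(ref$pop >= 0 & ref$pop <= 1))
  expect_error(tlbo_refine(pop, fit, sphere_fitness, refined_size = 30),
               "exceeds")
})

test_that("classical GA climbs the sphere benchmark monotonically", {
  sp <- hyperparam_space()
  cfg <- ga_config(population_size = 24, generations = 40, seed = 5)
  res <- classical_ga(sp, sphere_fitness, cfg)
  expect_gte(res$best_fitness, 0.95)
  expect_true(all(diff(res$trajectory) >= 0))      # elitism invariant
  expect_equal(res$best_fitness, sphere_fitness(res$best_genes))
  expect_gte(res$trajectory[res$first_attained + 1],
             res$best_fitness - 1e-4)
  expect_true(res$first_attained == 0 ||
                res$trajectory[res$first_attained] <
                  res$best_fitness - 1e-4)
  # deterministic under the seed
  res2 <- classical_ga(sp, sphere_fitness, cfg)
  expect_identical(res$trajectory, res2$trajectory)
})

test_that("TLBPSGA climbs the sphere and respects elitism and stagnation", {
  sp <- hyperparam_space()
  cfg <- ga_config(population_size = 24, refined_size = 12,
                   generations = 40, seed = 5)
  res <- tlbpsga(sp, sphere_fitness, cfg)
  expect_gte(res$best_fitness, 0.95)
  expect_true(all(diff(res$trajectory) >= 0))
  expect_lte(res$first_attained, cfg$generations)

  # rigged lattice fitness with a unique optimum is found
  target <- c(1, 0, 0.5, 1, 0, 0.5, 1)
  rigged <- function(genes) 1 - mean(abs(genes - target))
  cfg2 <- ga_config(population_size = 30, refined_size = 15,
                    generations = 50, seed = 9)
  res2 <- tlbpsga(sp, rigged, cfg2)
  expect_gte(res2$best_fitness, 0.9)
})

test_that("null dynamics leave the best solution untouched", {
  sp <- hyperparam_space()
  cfg <- ga_config(population_size = 12, refined_size = 12, generations = 10,
                   r_min = 0, r_max = 0, mutation_rate = 0,
                   refine_each_generation = FALSE, seed = 3,
                   stagnation_window = 100)
  res <- classical_ga(sp, sphere_fitness, cfg)
  expect_equal(res$trajectory, rep(res$trajectory[1], 11))
  expect_equal(res$first_attained, 0L)
})

test_that("the CV fitness is memoized, seeded and near chance on noise", {
  set.seed(44)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- rep(c(0L, 1L), 50)[sample.int(100)]
  sp <- hyperparam_space()
  f <- xgb_cv_fitness(X, y, sp, k = 5, seed = 2)
  g <- rep(0.5, 7)
  v1 <- f(g); v2 <- f(g)
  expect_identical(v1, v2)
  expect_equal(attr(f, "n_evaluations")(), 2L)
  expect_equal(attr(f, "n_unique")(), 1L)
  expect_gte(v1, 0.3)
  expect_lte(v1, 0.7)

  # separable data: any reasonable point scores high
  data <- make_gaussian_classes(50, d = 3, delta = 6, seed = 12)
  fs <- xgb_cv_fitness(data$X, data$y, sp, k = 5, seed = 2)
  expect_gte(fs(rep(0.5, 7)), 0.95)
})
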