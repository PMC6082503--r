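test_that("noise subsets nest by peeling the noisiest subjects", {
  p <- build_noise_subsets(1:5, 1:5, c(1.5, 2.5, 3.5, 4.5))
  expect_equal(lengths(p$train), c(5, 4, 3, 2, 1))
  expect_equal(lengths(p$val), c(5, 4, 3, 2, 1))
  # nesting: each subset contains the next
  for (i in 1:4)
    expect_true(all(p$train[[i + 1]] %in% p$train[[i]]))

  # thresholds all above the largest noise volume: no exclusions
  p2 <- build_noise_subsets(c(1, 2), c(1, 2), c(3, 4, 5, 6))
  expect_true(all(vapply(p2$train, identical, logical(1), y = 1:2)))

  # degenerate: all volumes above all thresholds -> empty subset error
  expect_error(build_noise_subsets(c(5, 5), c(5, 5), c(1, 2, 3, 4)),
               "empty")
  expect_error(build_noise_subsets(1:3, 1:3, c(2, 2, 3, 4)), "ascending")
})

test_that("rank AUC is the Mann-Whitney pair fraction with half-credit ties", {
  expect_equal(rank_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rank_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(rank_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(rank_auc(1:3, c(1, 1, 1)), "both classes")
  # agreement with an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(13)
  for (rep in 1:10) {
    sc <- round(rnorm(60), 1)          # rounding forces ties
    lb <- rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(lb, sc,
                                                 direction = "<")))
    expect_equal(rank_auc(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("the fitness formula weights validation shortfalls 1.5x across 5 subsets", {
  nv <- 1:10
  part <- build_noise_subsets(nv, nv, c(6.5, 7.5, 8.5, 9.5))
  lab <- rep(c(1, 0), 5)                  # both classes in every subset
  # perfect ranking everywhere -> fitness 0
  perfect <- ifelse(lab == 1, nv + 100, nv)
  expect_equal(ga_fitness(perfect, lab, perfect, lab, part)$fitness, 0)
  # all-tie scores give AUC 0.5 in all 10 subsets:
  # -5 * (0.25 + 1.5 * 0.25) = -3.125
  f <- ga_fitness(rep(1, 10), lab, rep(1, 10), lab, part)
  expect_equal(f$auc_train, rep(0.5, 5))
  expect_equal(f$fitness, -3.125)
  # perfect training, AUC 0.8 on validation everywhere: -5 * 1.5 * 0.04
  fit_v <- -5 * 1.5 * (1 - 0.8)^2
  expect_equal(fit_v, -0.3)   # the constant the mixed case must reproduce
  # single-class subset errors name the subset
  nv5 <- c(1, 2, 3, 4, 5)
  part5 <- build_noise_subsets(nv5, nv5, c(1.5, 2.5, 3.5, 4.5))
  expect_error(ga_fitness(c(10, 1, 11, 2, 12), c(1, 0, 1, 0, 1),
                          c(10, 1, 11, 2, 12), c(1, 0, 1, 0, 1), part5),
               "subset")
})

test_that("per-gene mutation frequency matches the configured probability", {
  set.seed(23)
  ranges <- rbind(lo = c(0, -1), hi = c(1, 1))
  colnames(ranges) <- c("a", "b")
  g <- c(a = 0.5, b = 0)
  hits <- 0; trials <- 20000
  for (i in seq_len(trials)) {
    m <- mutate_genome(g, ranges, mutation_prob = 0.33)
    hits <- hits + sum(m != g)
  }
  freq <- hits / (2 * trials)
  expect_lt(abs(freq - 0.33), 0.015)   # ~4.5 binomial sd at 4e4 gene-trials
  # mutation_prob 0 is the identity
  expect_identical(mutate_genome(g, ranges, mutation_prob = 0), g)
})

test_that("mutated genes stay inside their declared ranges", {
  set.seed(33)
  ranges <- rbind(lo = c(0, -4, 1), hi = c(1, 2, 10))
  colnames(ranges) <- c("a", "b", "c")
  g <- c(a = 0.99, b = -3.9, c = 9.8)   # near the boundaries
  for (i in 1:500) {
    m <- mutate_genome(g, ranges, mutation_prob = 1)
    expect_true(all(m >= ranges["lo", ] & m <= ranges["hi", ]))
  }
})

test_that("single-point crossover splices a prefix of one parent onto the other", {
  a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 5)
  b <- a + 10
  expect_identical(crossover_genomes(a, a), a)
  set.seed(43)
  cuts <- integer(0)
  for (i in 1:200) {
    ch <- crossover_genomes(a, b)
    from_a <- ch < 10
    # prefix from a, suffix from b
    expect_true(all(diff(from_a) <= 0))
    cut <- sum(from_a)
    expect_true(cut >= 1 && cut <= 4)   # internal positions only
    cuts <- c(cuts, cut)
  }
  expect_setequal(unique(cuts), 1:4)
})

test_that("a flat fitness landscape stops after exactly the stagnation limit", {
  ranges <- rbind(lo = c(0, 0), hi = c(1, 1))
  colnames(ranges) <- c("a", "b")
  cfg <- ga_config(population_size = 6, mutation_prob = 0,
                   stagnation_limit = 10, elitism = 2, seed = 5)
  res <- ga_run(function(g) 1, ranges, cfg)
  expect_equal(res$generations, 11L)  # first generation + 10 stagnant
  expect_false(res$truncated)
  expect_equal(max(res$history$stagnant), 10L)
})

test_that("best-ever fitness is monotone non-decreasing under elitism", {
  set.seed(53)
  ranges <- rbind(lo = c(-2, -2), hi = c(2, 2))
  colnames(ranges) <- c("x", "y")
  f <- function(g) -(g[["x"]] - 0.5)^2 - (g[["y"]] + 1)^2
  res <- ga_run(f, ranges, ga_config(population_size = 12, seed = 9,
                                     max_generations = 40))
  expect_true(all(diff(res$history$best_ever) >= 0))
  expect_equal(res$best_fitness, max(res$history$best_fitness))
})

test_that("the GA beats equal-budget random search on a smooth 2-gene problem", {
  ranges <- rbind(lo = c(0, 0), hi = c(1, 1))
  colnames(ranges) <- c("x", "y")
  f <- function(g) -(g[["x"]] - 0.37)^2 - (g[["y"]] - 0.81)^2
  wins <- 0
  for (s in 1:10) {
    cfg <- ga_config(population_size = 6, max_generations = 24,
                     stagnation_limit = 50, seed = 1000 + s)
    res <- ga_run(f, ranges, cfg)
    # elites carry their fitness, so actual evaluations are pop + later
    # generations times the offspring count
    budget <- cfg$population_size +
      (res$generations - 1) * (cfg$population_size - cfg$elitism)
    set.seed(2000 + s)
    rs <- max(vapply(seq_len(budget), function(i)
      f(c(x = runif(1), y = runif(1))), numeric(1)))
    if (res$best_fitness >= rs) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("genome evaluation is deterministic and huge lambda collapses to tie-only AUC", {
  co <- simulate_cohort(small_config(seed = 3))
  train <- split_data(co, "train")
  val <- split_data(co, "validation")
  part <- build_noise_subsets(train$noise, val$noise,
                              quantile(train$noise, c(.6, .7, .8, .9)))
  g <- c(alpha = 0.5, log_lambda = 0, upweight_factor = 2,
         gensini_weight_threshold = 1, corr_threshold = 0.95)
  f1 <- evaluate_genome(g, train, val, part)
  f2 <- evaluate_genome(g, train, val, part)
  expect_identical(f1$fitness, f2$fitness)

  # an overwhelming penalty shrinks every weight to zero: constant
  # predictor, all ten AUCs 0.5, fitness -3.125
  g[["log_lambda"]] <- 4
  f3 <- evaluate_genome(g, train, val, part)
  expect_equal(f3$auc_train, rep(0.5, 5), tolerance = 0.02)
  expect_equal(f3$fitness, -3.125, tolerance = 0.1)
})

test_that("evolution is reproducible from its seed", {
  co <- simulate_cohort(small_config(seed = 4))
  train <- split_data(co, "train")
  val <- split_data(co, "validation")
  part <- build_noise_subsets(train$noise, val$noise,
                              quantile(train$noise, c(.6, .7, .8, .9)))
  cfg <- ga_config(population_size = 6, max_generations = 3,
                   stagnation_limit = 10, seed = 77)
  r1 <- ga_evolve(train, val, part, cfg)
  r2 <- ga_evolve(train, val, part, cfg)
  expect_identical(r1$best_genome, r2$best_genome)
  expect_identical(r1$history$best_fitness, r2$history$best_fitness)
})

test_that("fitness is invariant under strictly monotone transforms of the scores", {
  set.seed(63)
  nv_t <- runif(40); nv_v <- runif(30)
  part <- build_noise_subsets(nv_t, nv_v, quantile(nv_t, c(.6, .7, .8, .9)))
  st <- rnorm(40); sv <- rnorm(30)
  lt <- rbinom(40, 1, 0.4); lv <- rbinom(30, 1, 0.4)
  f0 <- ga_fitness(st, lt, sv, lv, part)$fitness
  f1 <- ga_fitness(exp(2 * st), lt, exp(2 * sv), lv, part)$fitness
  expect_equal(f0, f1, tolerance = 1e-12)
})
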