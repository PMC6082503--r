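#' Genetic-algorithm configuration
#'
#' @param population_size Genomes per generation (>= 4).
#' @param mutation_prob Per-gene mutation probability (0.33 in the reference
#'   pipeline).
#' @param crossover_fraction Fraction of offspring built by single-point
#'   crossover of two parents (0.5 in the reference pipeline); the rest are
#'   clones of a single parent. All offspring then undergo mutation.
#' @param stagnation_limit Stop after this many consecutive generations
#'   without improvement of the best-ever fitness (10 in the reference
#'   pipeline).
#' @param elitism Number of top genomes copied unchanged into the next
#'   generation.
#' @param max_generations Hard safety cap; hitting it sets a truncation flag.
#' @param perturb_sd_frac Gaussian mutation spread as a fraction of the gene
#'   range.
#' @param seed Optional integer seed for a self-contained reproducible run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, mutation_prob = 0.33,
                      crossover_fraction = 0.5, stagnation_limit = 10L,
                      elitism = 2L, max_generations = 200L,
                      perturb_sd_frac = 0.1, seed = NULL) {
  if (population_size < 4) stop("population_size must be >= 4")
  if (mutation_prob < 0 || mutation_prob > 1 ||
      crossover_fraction < 0 || crossover_fraction > 1)
    stop("probabilities must lie in [0, 1]")
  if (elitism < 0 || elitism >= population_size)
    stop("elitism must be in [0, population_size)")
  if (stagnation_limit < 1 || max_generations < 1)
    stop("stagnation_limit and max_generations must be >= 1")
  structure(list(population_size = as.integer(population_size),
                 mutation_prob = mutation_prob,
                 crossover_fraction = crossover_fraction,
                 stagnation_limit = as.integer(stagnation_limit),
                 elitism = as.integer(elitism),
                 max_generations = as.integer(max_generations),
                 perturb_sd_frac = perturb_sd_frac,
                 seed = seed),
            class = "ga_config")
}

#' Gene ranges for the five-parameter CAD pipeline genome
#'
#' Genes, in order: elastic-net mixing `alpha` in \[0, 1\]; `log_lambda`
#' (log10 of the penalty strength) in \[-4, 2\]; `upweight_factor` in
#' \[1, 10\]; `gensini_weight_threshold` spanning the observed modified
#' Gensini range; `corr_threshold` in \[0.80, 1.0\].
#'
#' @param y Training-set modified Gensini scores (sets the threshold span).
#' @return A 2 x 5 matrix (rows `lo`, `hi`) with gene names as columns.
#' @export
cad_genome_ranges <- function(y) {
  rng <- range(y)
  m <- rbind(lo = c(0, -4, 1, rng[1], 0.80),
             hi = c(1,  2, 10, rng[2], 1.00))
  colnames(m) <- c("alpha", "log_lambda", "upweight_factor",
                   "gensini_weight_threshold", "corr_threshold")
  m
}

#' Rank (Mann-Whitney) AUC
#'
#' Fraction of (positive, negative) pairs in which the positive subject's
#' score exceeds the negative's, ties counted one half -- identical to the
#' area under the empirical ROC curve over all thresholds on the continuous
#' output.
#'
#' @param scores Continuous predictions.
#' @param labels Binary labels (0/1, logical, or `"positive"`/`"negative"`).
#' @return AUC in \[0, 1\].
#' @examples
#' rank_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
rank_auc <- function(scores, labels) {
  labels <- .as_binary(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

.as_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative")))
      stop("character labels must be 'positive'/'negative'")
    return(as.integer(labels == "positive"))
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  labels
}

#' Nested noise subsets from noise-volume thresholds
#'
#' Subset 1 contains every subject. Subsequent subsets peel off the noisiest
#' subjects: subset 2 excludes those above the largest threshold, subset 3
#' those above the next, and so on, so five nested subsets correspond to the
#' four ascending thresholds.
#'
#' @param noise_train,noise_val Noise volumes of the training and validation
#'   subjects.
#' @param thresholds Four strictly ascending noise-volume cutoffs.
#' @return An object of class `noise_partition` with `thresholds` and index
#'   lists `train` and `val` (each of length 5, nested).
#' @examples
#' p <- build_noise_subsets(1:5, 1:5, c(1.5, 2.5, 3.5, 4.5))
#' lengths(p$train)   # 5 4 3 2 1
#' @export
build_noise_subsets <- function(noise_train, noise_val, thresholds) {
  if (length(thresholds) != 4 || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be 4 strictly ascending values")
  subsets <- function(nv, which) {
    out <- vector("list", 5)
    out[[1]] <- seq_along(nv)
    for (i in 2:5) {
      out[[i]] <- which(nv <= thresholds[6 - i])
      if (length(out[[i]]) == 0)
        stop(sprintf("noise subset %s%d is empty (fitness undefined)",
                     which, i))
    }
    out
  }
  structure(list(thresholds = thresholds,
                 train = subsets(noise_train, "T"),
                 val = subsets(noise_val, "V")),
            class = "noise_partition")
}

#' Noise-subset-weighted AUC fitness
#'
#' The GA's objective:
#' \deqn{\mathrm{fitness} = -\sum_{i=1}^{5}\left[(1-\mathrm{AUC}(T_i))^2 +
#'   1.5\,(1-\mathrm{AUC}(V_i))^2\right]}
#' over the five nested training subsets \eqn{T_i} and validation subsets
#' \eqn{V_i}. It is nonpositive, and zero exactly when all ten AUCs equal 1.
#'
#' @param scores_train,scores_val Continuous model outputs.
#' @param labels_train,labels_val Binary CAD labels.
#' @param partition A [build_noise_subsets()] result.
#' @return A list with `fitness`, `auc_train` (5 values) and `auc_val`.
#' @export
ga_fitness <- function(scores_train, labels_train, scores_val, labels_val,
                       partition) {
  labels_train <- .as_binary(labels_train)
  labels_val <- .as_binary(labels_val)
  auc_of <- function(scores, labels, idx, name) {
    tryCatch(rank_auc(scores[idx], labels[idx]),
             error = function(e)
               stop(sprintf("subset %s: %s", name, conditionMessage(e)),
                    call. = FALSE))
  }
  auc_t <- vapply(1:5, function(i)
    auc_of(scores_train, labels_train, partition$train[[i]],
           paste0("T", i)), numeric(1))
  auc_v <- vapply(1:5, function(i)
    auc_of(scores_val, labels_val, partition$val[[i]],
           paste0("V", i)), numeric(1))
  list(fitness = -sum((1 - auc_t)^2 + 1.5 * (1 - auc_v)^2),
       auc_train = auc_t, auc_val = auc_v)
}

#' Evaluate one hyperparameter genome end to end
#'
#' Runs the full inner pipeline the GA scores: correlation reduction of the
#' training features at the genome's threshold, Gensini-threshold
#' upweighting, elastic-net fit on the training split, continuous
#' predictions on both splits, and the noise-subset-weighted AUC fitness
#' against the binary CAD labels.
#'
#' @param genome Named vector with genes `alpha`, `log_lambda`
#'   (log10 scale), `upweight_factor`, `gensini_weight_threshold`,
#'   `corr_threshold`.
#' @param train,val Lists with elements `x` (feature matrix), `gensini`
#'   (continuous target), `label` (binary CAD label) and `noise`
#'   (noise volumes).
#' @param partition A [build_noise_subsets()] result indexing into the two
#'   splits.
#' @param enet_tol,enet_max_sweeps Convergence controls passed to
#'   [enet_fit()].
#' @param cor_matrix Optional precomputed `abs(cor(train$x))`.
#' @return As [ga_fitness()], plus `reduction`, `fit` and `scores`.
#'   A genome whose reduction empties the feature set scores `-Inf`.
#' @export
evaluate_genome <- function(genome, train, val, partition,
                            enet_tol = 1e-5, enet_max_sweeps = 5000L,
                            cor_matrix = NULL) {
  genome <- unlist(genome)
  red <- reduce_by_correlation(train$x, genome[["corr_threshold"]],
                               cor_matrix = cor_matrix)
  kept <- red$kept_indices
  if (length(kept) == 0)
    return(list(fitness = -Inf, auc_train = rep(NA_real_, 5),
                auc_val = rep(NA_real_, 5), reduction = red,
                fit = NULL, scores = NULL))
  u <- apply_upweighting(train$gensini,
                         genome[["gensini_weight_threshold"]],
                         genome[["upweight_factor"]])
  fit <- enet_fit(train$x[, kept, drop = FALSE], train$gensini,
                  weights = u, alpha = genome[["alpha"]],
                  lambda = 10^genome[["log_lambda"]],
                  tol = enet_tol, max_sweeps = enet_max_sweeps)
  st <- predict(fit, train$x[, kept, drop = FALSE])
  sv <- predict(fit, val$x[, kept, drop = FALSE])
  out <- ga_fitness(st, train$label, sv, val$label, partition)
  out$reduction <- red
  out$fit <- fit
  out$scores <- list(train = st, val = sv)
  out
}

#' Mutate a genome
#'
#' Each gene independently mutates with probability `mutation_prob`; a
#' mutated gene is, with probability one half, perturbed by Gaussian noise
#' (sd = `perturb_sd_frac` of the gene range) and otherwise replaced by a
#' uniform draw over its range. Results are clipped to the declared ranges.
#'
#' @param genome Named numeric vector.
#' @param ranges 2 x k matrix of gene ranges (rows `lo`, `hi`).
#' @param mutation_prob Per-gene mutation probability.
#' @param perturb_sd_frac Gaussian spread as a fraction of the gene range.
#' @return Mutated genome.
#' @export
mutate_genome <- function(genome, ranges, mutation_prob = 0.33,
                          perturb_sd_frac = 0.1) {
  k <- length(genome)
  lo <- ranges["lo", ]; hi <- ranges["hi", ]
  hit <- runif(k) < mutation_prob
  if (any(hit)) {
    perturb <- runif(k) < 0.5
    span <- hi - lo
    new_g <- ifelse(perturb,
                    genome + rnorm(k, 0, perturb_sd_frac * span),
                    lo + runif(k) * span)
    genome[hit] <- new_g[hit]
    genome <- pmin(pmax(genome, lo), hi)
  }
  genome
}

#' Single-point crossover of two genomes
#'
#' A cut position is drawn uniformly from the internal positions of the
#' genome; genes up to the cut come from `parent_a`, the rest from
#' `parent_b`.
#'
#' @param parent_a,parent_b Named numeric vectors of equal length.
#' @return Offspring genome.
#' @export
crossover_genomes <- function(parent_a, parent_b) {
  k <- length(parent_a)
  if (length(parent_b) != k) stop("parents must have equal length")
  cut <- sample.int(k - 1, 1)
  c(parent_a[seq_len(cut)], parent_b[(cut + 1):k])
}

#' Run a genetic algorithm over an arbitrary fitness function
#'
#' Generic GA engine: uniform random initialisation over the gene ranges,
#' rank-weighted parent selection (cubic rank weights), offspring
#' production (a fixed fraction by single-point crossover, the rest cloned,
#' all mutated), elitism, and a stop rule of `stagnation_limit` consecutive
#' generations without strict improvement of the best-ever fitness.
#'
#' @param fitness_fn Function taking a named genome vector and returning a
#'   scalar fitness (larger is better; `-Inf` allowed).
#' @param ranges 2 x k matrix of gene ranges (rows `lo`, `hi`, named
#'   columns).
#' @param config A [ga_config()].
#' @return A list of class `ga_result`: `best_genome`, `best_fitness`,
#'   `history` (data frame with per-generation best/mean fitness and the
#'   generation-best genome), `generations`, `truncated`, `config`.
#' @export
ga_run <- function(fitness_fn, ranges, config = ga_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- ncol(ranges)
  gene_names <- colnames(ranges)
  npop <- config$population_size
  lo <- ranges["lo", ]; hi <- ranges["hi", ]

  pop <- matrix(runif(npop * k, rep(lo, each = npop), rep(hi, each = npop)),
                nrow = npop, ncol = k, dimnames = list(NULL, gene_names))
  fitness <- rep(NA_real_, npop)

  best_genome <- NULL
  best_fitness <- -Inf
  stagnant <- 0L
  truncated <- FALSE
  hist_rows <- vector("list", config$max_generations)
  gen <- 0L

  repeat {
    gen <- gen + 1L
    todo <- which(is.na(fitness))
    for (i in todo) fitness[i] <- fitness_fn(pop[i, ])

    gi <- which.max(fitness)
    finite <- fitness[is.finite(fitness)]
    if (is.null(best_genome) || fitness[gi] > best_fitness) {
      if (!is.null(best_genome)) stagnant <- 0L
      best_fitness <- fitness[gi]
      best_genome <- pop[gi, ]
    } else {
      stagnant <- stagnant + 1L
    }
    hist_rows[[gen]] <- data.frame(
      generation = gen,
      best_fitness = fitness[gi],
      best_ever = best_fitness,
      mean_fitness = if (length(finite)) mean(finite) else -Inf,
      stagnant = stagnant,
      as.list(pop[gi, ]))

    if (stagnant >= config$stagnation_limit) break
    if (gen >= config$max_generations) { truncated <- TRUE; break }

    # rank-weighted selection: cubic rank weights concentrate reproduction
    # on the best genomes, which pays off at small evaluation budgets while
    # the high per-gene mutation rate keeps exploration alive
    rk <- rank(fitness, ties.method = "first")^3
    sel_prob <- rk / sum(rk)
    ord <- order(fitness, decreasing = TRUE)
    n_elite <- config$elitism
    elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    elite_fit <- fitness[ord[seq_len(n_elite)]]

    n_off <- npop - n_elite
    n_cross <- round(config$crossover_fraction * n_off)
    offspring <- matrix(NA_real_, n_off, k, dimnames = list(NULL, gene_names))
    for (m in seq_len(n_off)) {
      child <- if (m <= n_cross) {
        ps <- sample.int(npop, 2, replace = FALSE, prob = sel_prob)
        crossover_genomes(pop[ps[1], ], pop[ps[2], ])
      } else {
        pop[sample.int(npop, 1, prob = sel_prob), ]
      }
      offspring[m, ] <- mutate_genome(child, ranges,
                                      config$mutation_prob,
                                      config$perturb_sd_frac)
    }
    pop <- rbind(elites, offspring)
    fitness <- c(elite_fit, rep(NA_real_, n_off))
  }

  structure(list(best_genome = best_genome,
                 best_fitness = best_fitness,
                 history = do.call(rbind, hist_rows[seq_len(gen)]),
                 generations = gen,
                 truncated = truncated,
                 config = config),
            class = "ga_result")
}

#' Evolve the five CAD-pipeline hyperparameters
#'
#' Wraps [ga_run()] around [evaluate_genome()]: every genome is scored by
#' running the reduction/upweighting/elastic-net pipeline and the
#' noise-subset-weighted AUC fitness. An elastic-net fit that fails to
#' converge within its sweep budget scores `-Inf` for that genome (logged),
#' rather than aborting the run.
#'
#' @param train,val Data lists as in [evaluate_genome()].
#' @param partition A [build_noise_subsets()] result.
#' @param config A [ga_config()].
#' @param ranges Gene ranges; default [cad_genome_ranges()] on the training
#'   target.
#' @param enet_tol,enet_max_sweeps Elastic-net convergence controls used for
#'   every genome evaluation.
#' @return A `ga_result` (see [ga_run()]).
#' @export
ga_evolve <- function(train, val, partition, config = ga_config(),
                      ranges = NULL, enet_tol = 1e-4,
                      enet_max_sweeps = 1500L) {
  if (is.null(ranges)) ranges <- cad_genome_ranges(train$gensini)
  cm <- abs(suppressWarnings(stats::cor(train$x)))
  fitness_fn <- function(genome) {
    tryCatch(
      evaluate_genome(genome, train, val, partition,
                      enet_tol = enet_tol,
                      enet_max_sweeps = enet_max_sweeps,
                      cor_matrix = cm)$fitness,
      cadnet_nonconvergence = function(e) -Inf)
  }
  ga_run(fitness_fn, ranges, config)
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA run: %d generations%s, best fitness %.6g\n",
              x$generations,
              if (x$truncated) " (truncated at cap)" else "",
              x$best_fitness))
  cat("  best genome:\n")
  print(round(x$best_genome, 5))
  invisible(x)
}
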