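#' Evolution configuration
#'
#' Hyperparameters of the Koza-style evolutionary loop. Defaults follow the
#' ranges used for the emulated study: population 150--250 (default 200),
#' 20--40 generations (default 30), crossover probability 0.6, mutation
#' probability 0.4, initial depth 3--5, tournament size 4 and a 5 x 5 pixel
#' neighborhood. Crossover and mutation apply or-else per offspring pair; a
#' static depth limit of 17 rejects bloated variation output (the parent is
#' kept instead).
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param p_crossover,p_mutation Variation probabilities (sum at most 1).
#' @param depth_range Initial tree depth range `c(min, max)`.
#' @param tournament_size Tournament size k.
#' @param patch_width Pixel-neighborhood side N (odd).
#' @param seed Integer seed for the whole evolution.
#' @param max_depth Static depth limit applied to variation output.
#' @return An object of class `digp_config`.
#' @export
evolution_config <- function(pop_size = 200, generations = 30,
                             p_crossover = 0.6, p_mutation = 0.4,
                             depth_range = c(3, 5), tournament_size = 4,
                             patch_width = 5, seed = 1, max_depth = 17) {
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1 ||
      p_crossover + p_mutation > 1 + 1e-12) {
    stop("variation probabilities must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  if (pop_size < tournament_size) {
    stop("`pop_size` must be at least `tournament_size`", call. = FALSE)
  }
  if (patch_width %% 2 != 1) stop("`patch_width` must be odd", call. = FALSE)
  if (depth_range[1] > depth_range[2] || depth_range[1] < 1) {
    stop("`depth_range` must be increasing and positive", call. = FALSE)
  }
  structure(
    list(pop_size = as.integer(pop_size), generations = as.integer(generations),
         p_crossover = p_crossover, p_mutation = p_mutation,
         depth_range = as.integer(depth_range),
         tournament_size = as.integer(tournament_size),
         patch_width = as.integer(patch_width), seed = as.integer(seed),
         max_depth = as.integer(max_depth)),
    class = "digp_config"
  )
}

# Ramped half-and-half without touching the RNG seed (callers seed).
make_population <- function(config, prims) {
  depths <- rep_len(seq(config$depth_range[1], config$depth_range[2]),
                    config$pop_size)
  methods <- rep_len(c("grow", "full"), config$pop_size)
  lapply(seq_len(config$pop_size), function(i) {
    random_tree(prims, config$depth_range[1], depths[i], methods[i])
  })
}

#' Initialize a GP population
#'
#' Ramped half-and-half initialization: tree depths cycle over the configured
#' range and generation methods alternate between "grow" and "full". Seeded by
#' `config$seed`; the same config yields an identical population.
#'
#' @param config An [evolution_config()].
#' @return A list of `pop_size` GP trees.
#' @export
init_population <- function(config) {
  prims <- gp_primitives(config$patch_width)
  withr::with_seed(config$seed, make_population(config, prims))
}

#' Variation: subtree crossover or mutation (or-else)
#'
#' With probability `p_crossover` the pair exchanges random subtrees;
#' otherwise with probability `p_mutation / (1 - p_crossover)`-complementary
#' draw (a single uniform draw ordering crossover, then mutation, then
#' reproduction) each parent has a random subtree replaced by a fresh random
#' tree of depth at most 2. Offspring deeper than `max_depth` are rejected and
#' the corresponding parent kept.
#'
#' @param parent1,parent2 GP trees.
#' @param p_crossover,p_mutation Probabilities (sum at most 1).
#' @param prims A [gp_primitives()] registry (defaults to 5 x 5).
#' @param max_depth Static depth limit.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A list of two offspring trees.
#' @export
vary <- function(parent1, parent2, p_crossover = 0.6, p_mutation = 0.4,
                 prims = gp_primitives(), max_depth = 17, seed = NULL) {
  run <- function() {
    u <- stats::runif(1)
    kids <- if (u < p_crossover) {
      i1 <- sample.int(tree_size(parent1), 1L)
      i2 <- sample.int(tree_size(parent2), 1L)
      s1 <- get_subtree(parent1, i1)
      s2 <- get_subtree(parent2, i2)
      list(replace_subtree(parent1, i1, s2), replace_subtree(parent2, i2, s1))
    } else if (u < p_crossover + p_mutation) {
      mutate_one <- function(p) {
        i <- sample.int(tree_size(p), 1L)
        replace_subtree(p, i, random_tree(prims, 0, 2, "grow"))
      }
      list(mutate_one(parent1), mutate_one(parent2))
    } else {
      list(parent1, parent2)
    }
    if (tree_depth(kids[[1]]) > max_depth) kids[[1]] <- parent1
    if (tree_depth(kids[[2]]) > max_depth) kids[[2]] <- parent2
    kids
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Tournament selection
#'
#' Each selection draws `k` individuals uniformly with replacement and returns
#' the one with the lowest cost (ties resolved to the earliest drawn index,
#' keeping selection deterministic given the RNG stream).
#'
#' @param population List of individuals.
#' @param fitnesses Numeric cost per individual (lower is better).
#' @param k Tournament size.
#' @param n_select Number of individuals to select.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A list of `n_select` selected individuals (copies).
#' @export
tournament_select <- function(population, fitnesses, k = 4,
                              n_select = length(population), seed = NULL) {
  n <- length(population)
  if (n == 0L) stop("empty population", call. = FALSE)
  if (k > n) stop("`k` cannot exceed the population size", call. = FALSE)
  run <- function() {
    idx <- vapply(seq_len(n_select), function(i) {
      cand <- sample.int(n, k, replace = TRUE)
      cand[which.min(fitnesses[cand])]
    }, integer(1))
    population[idx]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Patch matrix: one row per interior pixel (column-major interior order), one
# column per patch pixel in row-major patch numbering.
patch_matrix <- function(M, patch_width = 5) {
  h <- patch_width %/% 2L
  nr <- nrow(M) - 2L * h
  nc <- ncol(M) - 2L * h
  if (nr < 1L || nc < 1L) {
    stop(sprintf("image must be at least %d x %d", patch_width, patch_width),
         call. = FALSE)
  }
  P <- matrix(0, nr * nc, patch_width^2)
  k <- 0L
  for (di in -h:h) {
    for (dj in -h:h) {
      k <- k + 1L
      P[, k] <- as.vector(M[(1L + h + di):(h + nr + di),
                            (1L + h + dj):(h + nc + dj)])
    }
  }
  P
}

# Flattened (column-major) indices of the interior pixels of an nr x nc image.
interior_indices <- function(nr, nc, patch_width = 5) {
  h <- patch_width %/% 2L
  rows <- (h + 1L):(nr - h)
  cols <- (h + 1L):(nc - h)
  as.vector(outer(rows, (cols - 1L) * nr, "+"))
}

#' Sliding-window image reconstruction
#'
#' Applies a GP individual pixel by pixel: every pixel whose full N x N
#' neighborhood lies inside the measurement image gets the tree's (clipped)
#' output; margin pixels with incomplete neighborhoods are skipped and written
#' as 0. The output has the same shape as the input.
#'
#' @param tree A GP tree.
#' @param M Measurement image (matrix, at least N x N).
#' @param patch_width Neighborhood side N (default 5).
#' @return A matrix in [0, 1] with zero margins.
#' @export
reconstruct_image <- function(tree, M, patch_width = 5) {
  P <- patch_matrix(M, patch_width)
  v <- eval_tree_matrix(tree, P)
  h <- patch_width %/% 2L
  out <- matrix(0, nrow(M), ncol(M))
  out[(h + 1L):(nrow(M) - h), (h + 1L):(ncol(M) - h)] <- v
  out
}

#' Run the evolutionary loop
#'
#' Generational GP with tournament selection, or-else subtree
#' crossover/mutation, hall-of-fame elitism of size 1 and a static depth
#' limit. Fitness is evaluated with the composite physics/MSE/Dice cost over
#' the dataset's training split (see [combined_fitness()]); the whole run is
#' driven by `config$seed` and is bitwise reproducible.
#'
#' @param dataset A [build_dataset()] object (its training split is used).
#' @param config An [evolution_config()].
#' @param weights A [fitness_weights()] object.
#' @param verbose Print per-generation progress.
#' @return An object of class `digp_fit`: list with `best_tree`,
#'   `best_fitness`, `history` (tibble: generation, best, mean, best_so_far),
#'   `config`, `weights`.
#' @export
evolve <- function(dataset, config = evolution_config(),
                   weights = fitness_weights(), verbose = FALSE) {
  stopifnot(inherits(dataset, "digp_dataset"))
  if (length(dataset$train_idx) == 0L) {
    stop("training split is empty", call. = FALSE)
  }
  prims <- gp_primitives(config$patch_width)
  evaluator <- make_batch_evaluator(dataset, config, weights)

  withr::with_seed(config$seed, {
    pop <- make_population(config, prims)
    fits <- evaluator(pop)
    if (all(!is.finite(fits))) stop("all fitness values are infinite", call. = FALSE)
    hof_i <- which.min(fits)
    hof <- pop[[hof_i]]
    hof_fit <- fits[hof_i]
    history <- vector("list", config$generations + 1L)
    history[[1]] <- c(generation = 0, best = min(fits), mean = mean(fits),
                      best_so_far = hof_fit)

    for (gen in seq_len(config$generations)) {
      parents <- tournament_select(pop, fits, config$tournament_size,
                                   config$pop_size)
      offspring <- vector("list", config$pop_size)
      i <- 1L
      while (i <= config$pop_size) {
        j <- if (i == config$pop_size) 1L else i + 1L
        kids <- vary(parents[[i]], parents[[j]], config$p_crossover,
                     config$p_mutation, prims, config$max_depth)
        offspring[[i]] <- kids[[1]]
        if (i + 1L <= config$pop_size) offspring[[i + 1L]] <- kids[[2]]
        i <- i + 2L
      }
      offspring[[1L]] <- hof # elitism: the best-so-far survives
      pop <- offspring
      fits <- evaluator(pop)
      gi <- which.min(fits)
      if (fits[gi] < hof_fit) {
        hof <- pop[[gi]]
        hof_fit <- fits[gi]
      }
      history[[gen + 1L]] <- c(generation = gen, best = min(fits),
                               mean = mean(fits), best_so_far = hof_fit)
      if (verbose) {
        message(sprintf("gen %3d  best %.5f  mean %.5f  best-so-far %.5f",
                        gen, min(fits), mean(fits), hof_fit))
      }
    }
  })

  hist <- tibble::as_tibble(do.call(rbind, history))
  structure(
    list(best_tree = hof, best_fitness = hof_fit, history = hist,
         config = config, weights = weights),
    class = "digp_fit"
  )
}

#' @export
print.digp_fit <- function(x, ...) {
  cat("<digp_fit>\n")
  cat(sprintf("  best cost  %.6f after %d generations (pop %d)\n",
              x$best_fitness, x$config$generations, x$config$pop_size))
  cat(sprintf("  best tree  %d nodes, depth %d\n",
              tree_size(x$best_tree), tree_depth(x$best_tree)))
  cat("  ", substr(serialize_tree(x$best_tree), 1, 70), "...\n", sep = "")
  invisible(x)
}

# Batched population evaluator. Stacks the patch matrices of all training
# samples so each tree is evaluated once per generation, then scores the
# physics, MSE and Dice components with dense matrix products. Matches
# combined_fitness() tree by tree (tested).
make_batch_evaluator <- function(dataset, config, weights) {
  idx <- dataset$train_idx
  geom <- dataset$geom
  N <- config$patch_width
  nr <- geom$grid[1]; nc <- geom$grid[2]
  interior <- interior_indices(nr, nc, N)
  n_int <- length(interior)
  Jpos_int <- -jacobian_entries(dataset$J)[, interior, drop = FALSE]

  P_all <- do.call(rbind, lapply(idx, function(i) {
    patch_matrix(dataset$samples[[i]]$measurement$M_sub, N)
  }))
  rows <- lapply(seq_along(idx), function(s) ((s - 1) * n_int + 1):(s * n_int))

  per_sample <- lapply(idx, function(i) {
    m <- dataset$samples[[i]]$measurement
    a <- dataset$samples[[i]]$anomaly
    meas <- as.numeric(m$M_sub)
    mmax <- max(meas)
    if (mmax > 0) meas <- meas / mmax
    mask <- which(as.numeric(m$snr_mask) > 0)
    g <- as.numeric(a$contrast)
    list(meas_masked = meas[mask], mask = mask,
         g_int = g[interior], g_sq_total = sum(g^2),
         g_margin_sq = sum(g[-interior]^2))
  })

  alpha <- weights$alpha; beta <- weights$beta; gamma <- weights$gamma
  n_samp <- length(idx)

  function(pop) {
    n_pop <- length(pop)
    Chi <- matrix(0, nrow(P_all), n_pop)
    for (j in seq_len(n_pop)) Chi[, j] <- eval_tree_matrix(pop[[j]], P_all)
    total <- numeric(n_pop)
    for (s in seq_len(n_samp)) {
      ps <- per_sample[[s]]
      Cs <- Chi[rows[[s]], , drop = FALSE]
      pred <- Jpos_int %*% Cs # full detector frame per individual
      pmax_col <- apply(pred, 2, max)
      f <- numeric(n_pop)
      if (alpha > 0) {
        predm <- pred[ps$mask, , drop = FALSE]
        scale <- ifelse(pmax_col > 0, pmax_col, 1)
        predm <- sweep(predm, 2, scale, "/")
        f <- f + alpha * colMeans((predm - ps$meas_masked)^2)
      }
      if (beta > 0) {
        f <- f + beta * (colSums((Cs - ps$g_int)^2) + ps$g_margin_sq) /
          (nr * nc)
      }
      if (gamma > 0) {
        cross <- as.numeric(crossprod(Cs, ps$g_int))
        sx <- colSums(Cs^2)
        f <- f + gamma * (1 - 2 * cross / (sx + ps$g_sq_total + 1e-8))
      }
      total <- total + f
    }
    total / n_samp
  }
}
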