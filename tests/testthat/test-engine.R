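test_that("population initialization is ramped, sized and seeded", {
  cfg <- evolution_config(pop_size = 200, generations = 1, seed = 5)
  pop <- init_population(cfg)
  expect_length(pop, 200)
  depths <- vapply(pop, tree_depth, integer(1))
  expect_true(all(depths >= 3 & depths <= 5))
  pop2 <- init_population(cfg)
  expect_identical(vapply(pop, serialize_tree, character(1)),
                   vapply(pop2, serialize_tree, character(1)))
})

test_that("variation respects probabilities, closure and the depth cap", {
  prims <- gp_primitives()
  p1 <- parse_tree("(Add Pixel1 (Multiply Pixel2 0.5))")
  p2 <- parse_tree("(Complement (Min3 Pixel3 Pixel4 0.25))")
  # no-op variation returns the parents unchanged
  kids <- vary(p1, p2, p_crossover = 0, p_mutation = 0, seed = 1)
  expect_identical(serialize_tree(kids[[1]]), serialize_tree(p1))
  expect_identical(serialize_tree(kids[[2]]), serialize_tree(p2))
  # offspring always parse back (structural closure / arity invariants)
  withr::with_seed(42, {
    for (i in 1:200) {
      k <- vary(p1, p2, 0.6, 0.4, prims)
      for (t in k) {
        txt <- serialize_tree(t)
        expect_identical(serialize_tree(parse_tree(txt)), txt)
      }
    }
  })
  # mutation fires at its nominal Bernoulli rate (40% +/- 5%)
  fired <- withr::with_seed(9, vapply(1:1000, function(i) {
    k <- vary(p1, p2, p_crossover = 0, p_mutation = 0.4, prims = prims)
    !identical(serialize_tree(k[[1]]), serialize_tree(p1))
  }, logical(1)))
  expect_gt(mean(fired), 0.35)
  expect_lt(mean(fired), 0.45)
  # offspring beyond the static depth limit are rejected in favor of parents
  deep <- p1
  for (i in 1:17) deep <- digp:::node_fun("Minus", list(deep), prims)
  kd <- vary(deep, deep, p_crossover = 1, p_mutation = 0, prims = prims,
             max_depth = 17, seed = 3)
  expect_lte(tree_depth(kd[[1]]), 17 + tree_depth(p1)) # never unbounded
})

test_that("tournament selection prefers low cost at the textbook rate", {
  pop <- as.list(letters[1:10])
  fit <- 1:10 # individual "a" is strictly best
  picks <- withr::with_seed(21, vapply(1:10000, function(i) {
    tournament_select(pop, fit, k = 4, n_select = 1)[[1]]
  }, character(1)))
  p_best <- mean(picks == "a")
  # with replacement: P(best selected) = 1 - (1 - 1/n)^k
  expect_lt(abs(p_best - (1 - 0.9^4)), 0.02)
  # equal fitness: selection is uniform (chi-square at alpha = 0.01)
  eq <- withr::with_seed(22, vapply(1:10000, function(i) {
    tournament_select(pop, rep(1, 10), k = 4, n_select = 1)[[1]]
  }, character(1)))
  chisq <- sum((table(eq) - 1000)^2 / 1000)
  expect_lt(chisq, stats::qchisq(0.99, df = 9))
  expect_error(tournament_select(list(), numeric(0)), "empty")
  expect_error(tournament_select(pop, fit, k = 11), "exceed")
})

test_that("sliding-window reconstruction fills the interior and zeroes margins", {
  M <- withr::with_seed(2, matrix(stats::runif(64 * 64), 64, 64))
  id <- parse_tree("Pixel13") # center pixel of the 5 x 5 patch
  out <- reconstruct_image(id, M)
  expect_equal(dim(out), c(64, 64))
  expect_equal(out[3:62, 3:62], M[3:62, 3:62])
  expect_true(all(out[1:2, ] == 0) && all(out[, 1:2] == 0))
  expect_true(all(out[63:64, ] == 0) && all(out[, 63:64] == 0))
  one <- reconstruct_image(parse_tree("1.0"), M)
  expect_equal(sum(one), 60 * 60) # interior is 64 - (N - 1) = 60 per side
  expect_true(all(out >= 0 & out <= 1))
  expect_error(reconstruct_image(id, matrix(0, 4, 4)), "at least 5 x 5")
})

test_that("evolution is monotone in best-so-far and bitwise reproducible", {
  ds <- small_dataset()
  cfg <- evolution_config(pop_size = 16, generations = 3, seed = 13)
  f1 <- evolve(ds, cfg)
  expect_true(all(diff(f1$history$best_so_far) <= 0))
  f2 <- evolve(ds, cfg)
  expect_identical(serialize_tree(f1$best_tree), serialize_tree(f2$best_tree))
  expect_identical(f1$history, f2$history)
  expect_s3_class(f1$history, "tbl_df")
  expect_equal(nrow(f1$history), 4) # generation 0 plus 3 generations
})

test_that("the batched population evaluator matches combined_fitness", {
  ds <- small_dataset()
  cfg <- evolution_config(pop_size = 8, generations = 1, seed = 3)
  w <- fitness_weights()
  ev <- digp:::make_batch_evaluator(ds, cfg, w)
  pop <- init_population(cfg)
  batch <- ev(pop)
  direct <- vapply(pop, combined_fitness, numeric(1),
                   samples = ds$samples[ds$train_idx], J = ds$J, weights = w)
  expect_equal(batch, direct, tolerance = 1e-12)
})

test_that("evolution recovers a planted center-pixel mapping", {
  # ground truth := center pixel of each measurement; pure-MSE objective.
  # An identity-like individual (Pixel13) is optimal, so evolved cost must
  # drop below the best constant-tree baseline in most seeded runs.
  ds <- small_dataset()
  planted <- ds
  planted$samples <- lapply(ds$samples, function(s) {
    s$anomaly$contrast <- reconstruct_image(parse_tree("Pixel13"),
                                            s$measurement$M_sub)
    s
  })
  w <- fitness_weights(alpha = 0, beta = 1, gamma = 0)
  const_costs <- vapply(seq(0, 1, 0.05), function(cc) {
    combined_fitness(parse_tree(sprintf("%.2f", cc)),
                     planted$samples[planted$train_idx], planted$J, w)
  }, numeric(1))
  baseline <- min(const_costs)
  wins <- 0
  for (s in 1:5) {
    cfg <- evolution_config(pop_size = 30, generations = 6, seed = 100 + s)
    fit <- evolve(planted, cfg, w)
    if (fit$best_fitness < baseline) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
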