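test_that("route_length sums consecutive Euclidean legs of an open path", {
  pb <- make_maze("pegboard")
  two <- toy_layout(pb, rbind(c(10, 10), c(30, 10)), c(0L, 0L))
  expect_equal(route_length(1:2, two), 20)
  # 3-4-5 right triangle, open path: 3 + 4, the 5 leg is never closed
  tri <- toy_layout(pb, rbind(c(10, 13), c(10, 10), c(14, 10)), c(0L, 0L))
  expect_equal(route_length(c(1, 2, 3), tri), 7)
  expect_equal(route_length(c(1, 3, 2), tri), 5 + 4)
  expect_error(route_length(c(1, 1, 2), tri), "permutation")
  expect_error(route_length(1:2, tri), "permutation")
})

test_that("any permutation is at least as long as the end-to-end chord", {
  set.seed(44)
  lay <- generate_layout(make_maze("lattice"), c(0L, 0L, 0L), seed = 44)
  for (i in 1:10) {
    ord <- sample(24)
    chord <- sqrt(sum((lay$baited_phys[ord[1], ] - lay$baited_phys[ord[24], ])^2))
    expect_gte(route_length(ord, lay), chord)
  }
})

test_that("the anchor is the baited position adjacent to the start on X", {
  pb <- make_maze("pegboard")
  lay <- generate_layout(pb, c(0L, 0L), seed = 2)
  a <- anchor_index(lay)
  expect_equal(unname(lay$baited_grid[a, ]), c(1L, 0L))
  lay2 <- generate_layout(pb, c(4L, 4L), seed = 2)
  expect_equal(unname(lay2$baited_grid[anchor_index(lay2), ]), c(3L, 4L))
})

test_that("evolve solves collinear instances exactly", {
  pb <- make_maze("pegboard")
  # 5 equally spaced points on one row; the anchor is the second point
  # (nearest bin (1,0)), so the optimum doubles back once then sweeps
  lay <- toy_layout(pb, cbind(seq(10, 90, by = 20), 10), c(0L, 0L))
  r <- evolve(lay, ga_config(n_restarts = 3, n_generations = 300, seed = 5))
  bf <- brute_force_route(lay, anchor_index(lay))
  expect_equal(r$length, bf$length)
})

test_that("evolve is deterministic given a seed and tracks its incumbent", {
  lay <- generate_layout(make_maze("lattice"), c(0L, 0L, 3L), seed = 10)
  cfg <- ga_config(n_restarts = 2, n_generations = 200, seed = 33)
  a <- evolve(lay, cfg)
  b <- evolve(lay, cfg)
  expect_identical(a$order, b$order)
  expect_identical(a$length, b$length)
  # the returned route is the best over restarts
  expect_equal(a$length, min(a$restart_best))
  expect_equal(a$order[1], anchor_index(lay))
  expect_setequal(a$order, 1:24)
})

test_that("evolve matches the exhaustive optimum on small instances", {
  pb <- make_maze("pegboard")
  set.seed(71)
  hits <- 0
  n_cases <- 12
  for (i in 1:n_cases) {
    k <- sample(5:7, 1)
    phys <- cbind(runif(k, 0, 100), runif(k, 0, 100))
    lay <- toy_layout(pb, phys, c(0L, 0L))
    ga <- evolve(lay, ga_config(n_restarts = 5, n_generations = 500,
                                seed = 1000 + i))
    bf <- brute_force_route(lay, anchor_index(lay))
    if (isTRUE(all.equal(ga$length, bf$length))) hits <- hits + 1
  }
  expect_equal(hits, n_cases)
})

test_that("pooled optimised references report mean and SEM per mode", {
  pb <- make_maze("pegboard")
  layouts <- lapply(1:4, function(i) {
    generate_layout(pb, maze_corners(pb)[i, ], trial_id = i, seed = 60 + i)
  })
  ref <- optimised_reference(layouts, ga_config(n_restarts = 3,
                                                n_generations = 400,
                                                seed = 77))
  expect_setequal(ref$od_summary$mode, c("layer", "column"))
  expect_equal(ref$od_summary$n, c(4L, 4L))
  expect_true(all(ref$od_summary$sem > 0))
  expect_setequal(ref$crossing_summary$axis, c("X", "Z"))
  expect_equal(nrow(ref$per_trial_od), 8)
  # determinism of the pooled run
  ref2 <- optimised_reference(layouts, ga_config(n_restarts = 3,
                                                 n_generations = 400,
                                                 seed = 77))
  expect_equal(ref$od_summary, ref2$od_summary)
})

test_that("when a snake is distance-optimal the optimised OD matches it", {
  pb <- make_maze("pegboard")
  # single-row layout: the only distance-optimal route is the sorted
  # line, which is also the layer_snake order
  lay <- toy_layout(pb, cbind(seq(10, 90, by = 20), 10), c(0L, 0L))
  r <- evolve(lay, ga_config(n_restarts = 2, n_generations = 200, seed = 3))
  snake <- simulate_visits(lay, "layer_snake")
  expect_equal(od_per_group(r, "layer")$mean_od,
               od_per_group(snake, "layer")$mean_od)
})

test_that("ga_config validates the survivor arithmetic", {
  expect_error(ga_config(population_size = 99))
  expect_error(ga_config(group_size = 5))
  expect_error(evolve(toy_layout(make_maze("pegboard"),
                                 rbind(c(10, 10)), c(0L, 0L)),
                      ga_config()), "at least 2")
})
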