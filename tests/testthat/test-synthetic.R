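test_that("pegboard layouts bait one jittered peg in each of the 25 regions", {
  pb <- make_maze("pegboard")
  lay <- generate_layout(pb, c(0L, 0L), seed = 11)
  expect_equal(nrow(lay$baited_grid), 25)
  expect_identical(anyDuplicated(as.data.frame(lay$baited_grid)), 0L)
  offs <- lay$baited_phys - to_physical(lay$baited_grid, pb)
  expect_true(all(abs(offs) == 5))  # one of the 4 pegs of the 2x2 array

  expect_identical(generate_layout(pb, c(0L, 0L), seed = 11)$baited_phys,
                   lay$baited_phys)
  expect_error(generate_layout(pb, c(2L, 0L), seed = 1), "corner")
})

test_that("lattice layouts bait 6 of 25 intersections per layer", {
  lt <- make_maze("lattice")
  lay <- generate_layout(lt, c(0L, 0L, 3L), seed = 5)
  expect_equal(nrow(lay$baited_grid), 24)
  expect_equal(as.vector(table(lay$baited_grid[, 3])), rep(6L, 4))
  # physical X/Y on intersection points, snapped grid indices valid
  expect_true(all(lay$baited_phys[, 1:2] %% 12.5 == 0))
  expect_true(all(lay$baited_grid >= 0 & lay$baited_grid <= 3))
  # snapping: intersection i maps to cube max(i-1, 0)
  expect_equal(lay$baited_grid[, 1], pmax(lay$baited_phys[, 1] / 12.5 - 1, 0))
})

test_that("layout CSV round-trips", {
  lay <- generate_layout(make_maze("lattice"), c(0L, 0L, 0L), seed = 2)
  tmp <- tempfile(fileext = ".csv")
  write_layout_csv(lay, tmp)
  back <- read_layout_csv(tmp)
  expect_identical(back$baited_grid, lay$baited_grid)
  expect_equal(back$baited_phys, lay$baited_phys)
  expect_identical(back$start, unname(lay$start))
})

test_that("snake strategies sweep bands with consecutive ordinals", {
  pb <- make_maze("pegboard")
  lay <- generate_layout(pb, c(0L, 0L), seed = 7)
  sn <- simulate_visits(lay, "layer_snake")
  bands <- group_of(lay$baited_grid[sn$order, ], pb, "layer")
  for (b in unique(bands)) {
    ords <- which(bands == b)
    expect_equal(ords, min(ords):(min(ords) + 4))  # 5 consecutive ordinals
  }
  # transpose property
  cs <- simulate_visits(lay, "column_snake")
  cbands <- group_of(lay$baited_grid[cs$order, ], pb, "column")
  for (b in unique(cbands)) {
    ords <- which(cbands == b)
    expect_equal(ords, min(ords):(min(ords) + 4))
  }
  # start corner at the top flips the sweep direction
  top <- simulate_visits(generate_layout(pb, c(0L, 4L), seed = 7), "layer_snake")
  expect_equal(group_of(top$layout$baited_grid[top$order[1], ], pb, "layer"), 4L)
})

test_that("random orders are anchored, reproducible permutations", {
  lay <- generate_layout(make_maze("pegboard"), c(4L, 4L), seed = 3)
  a <- simulate_visits(lay, "random_order", seed = 21)
  b <- simulate_visits(lay, "random_order", seed = 21)
  expect_identical(a$order, b$order)
  expect_setequal(a$order, 1:25)
  start_xy <- to_physical(lay$start, lay$maze)[1, ]
  d <- colSums((t(lay$baited_phys) - start_xy)^2)
  expect_equal(a$order[1], which.min(d))
})

test_that("greedy agent on collinear baits walks the line in order", {
  pb <- make_maze("pegboard")
  phys <- cbind(seq(10, 90, by = 20), 10)  # one row of 5
  lay <- toy_layout(pb, phys, c(0L, 0L))
  g <- simulate_visits(lay, "greedy_nearest")
  expect_identical(g$order, 1:5)
})

test_that("trajectories sample the path at constant speed", {
  pb <- make_maze("pegboard")
  lay <- toy_layout(pb, rbind(c(10, 10), c(30, 10)), c(0L, 0L))
  tr <- visits_to_trajectory(toy_sequence(lay, 1:2), sampling_rate = 10, speed = 10)
  expect_equal(nrow(tr$samples), 21)            # 2 s at 10 Hz
  expect_equal(tr$samples$t[21], 2)
  expect_equal(tr$samples$X, seq(10, 30, by = 1))

  single <- visits_to_trajectory(toy_sequence(lay, 1L))
  expect_equal(nrow(single$samples), 1)

  full <- visits_to_trajectory(simulate_visits(generate_layout(pb, c(0L, 0L),
                                                               seed = 1),
                                               "greedy_nearest"))
  xy <- as.matrix(full$samples[, c("X", "Z")])
  expect_true(all(xy >= 0 & xy <= 100))
})

test_that("detour simulation respects the choice probabilities", {
  all_h <- simulate_detours(c(up = 1), n_rats = 4, n_trials_per_rat = 5, seed = 1)
  expect_true(all(all_h$choice == "horizontal_first"))
  all_v <- simulate_detours(c(down = 0), n_rats = 4, n_trials_per_rat = 5, seed = 1)
  expect_true(all(all_v$choice == "vertical_first"))

  big <- simulate_detours(c(up = 0.5), n_rats = 60, n_trials_per_rat = 50, seed = 9)
  p_hat <- mean(big$choice == "horizontal_first")
  se <- sqrt(0.25 / nrow(big))
  expect_lt(abs(p_hat - 0.5), 3 * se)

  expect_identical(simulate_detours(c(up = 0.3), seed = 4),
                   simulate_detours(c(up = 0.3), seed = 4))
})
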