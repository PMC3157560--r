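test_that("band ordinal distances match hand-enumerated pairs", {
  pb <- make_maze("pegboard")
  # two baits in one layer retrieved 1st and 2nd -> OD 1
  lay2 <- toy_layout(pb, rbind(c(10, 10), c(50, 10)), c(0L, 0L))
  r <- od_per_group(toy_sequence(lay2, 1:2), "layer")
  expect_equal(r$mean_od, 1)
  # ordinals {1,3,7} in one layer: pairs |1-3|,|1-7|,|3-7| -> (2+6+4)/3
  lay3 <- toy_layout(pb, rbind(c(10, 10), c(30, 30), c(50, 10), c(70, 30),
                               c(90, 30), c(10, 30), c(90, 10)), c(0L, 0L))
  # layer 0 holds rows 1,3,7 -> give them ordinals 1,3,7
  ord <- c(1, 2, 3, 4, 5, 6, 7)
  vs <- toy_sequence(lay3, ord)  # ordinal k = position visited k-th
  res <- od_per_group(vs, "layer")
  band0 <- res$per_group[res$per_group$group == 0, ]
  expect_equal(band0$od, od_brute(c(1, 3, 7)))
  expect_equal(band0$od, 4)
  expect_equal(band0$n, 3)
})

test_that("the pegboard boustrophedon gives layer OD 2 and column OD 10", {
  sn <- pegboard_snake_layout(seed = 9)
  lay_od <- od_per_group(sn, "layer")
  col_od <- od_per_group(sn, "column")
  expect_equal(lay_od$mean_od, 2)
  expect_equal(col_od$mean_od, 10)
  expect_equal(lay_od$p, 5)
  expect_true(all(lay_od$per_group$n == 5))
})

test_that("OD agrees with the brute-force pair enumeration on random orders", {
  set.seed(5)
  lt <- make_maze("lattice")
  for (i in 1:5) {
    lay <- generate_layout(lt, c(0L, 0L, 0L), seed = 40 + i)
    vs <- toy_sequence(lay, sample(24))
    for (mode in maze_modes(lt)) {
      r <- od_per_group(vs, mode)
      bands <- group_of(lay$baited_grid[vs$order, ], lt, mode)
      manual <- sapply(sort(unique(bands)), function(b) {
        x <- which(bands == b)
        if (length(x) < 2) NA_real_ else od_brute(x)
      })
      expect_equal(r$mean_od, mean(manual, na.rm = TRUE))
    }
  }
})

test_that("OD is invariant under reversing the visit order", {
  set.seed(6)
  lay <- generate_layout(make_maze("pegboard"), c(4L, 4L), seed = 17)
  for (i in 1:10) {
    ord <- sample(25)
    fwd <- od_per_group(toy_sequence(lay, ord), "layer")$mean_od
    bwd <- od_per_group(toy_sequence(lay, base::rev(ord)), "layer")$mean_od
    expect_equal(fwd, bwd)
  }
})

test_that("groups below two retrievals are dropped; p = 0 is an error", {
  pb <- make_maze("pegboard")
  # one bait per layer -> no valid band
  lay <- toy_layout(pb, rbind(c(10, 10), c(10, 30), c(10, 50)), c(0L, 0L))
  expect_error(od_per_group(toy_sequence(lay, 1:3), "layer"), "p = 0")
  # same sequence grouped by column: all three share column 0 -> valid
  expect_equal(od_per_group(toy_sequence(lay, 1:3), "column")$p, 1)
})

test_that("OD ratios divide observed by optimised and carry both", {
  mk <- function(v, mode = "layer") structure(
    list(mode = mode, per_group = NULL, mean_od = v, p = 5),
    class = "od_result")
  expect_equal(round(od_ratio(mk(3.8), mk(5.12))$ratio, 3), 0.742)
  expect_equal(round(od_ratio(mk(7.73), mk(5.14))$ratio, 3), 1.504)
  expect_equal(od_ratio(mk(4.4), mk(4.4))$ratio, 1)
  expect_error(od_ratio(mk(1, "layer"), mk(1, "column")), "mode")
  expect_error(od_ratio(mk(1), mk(0)))
})

test_that("random-order ODs match the closed-form null (N+1)/3", {
  null <- od_expectation_random(make_maze("pegboard"), "layer",
                                n_mc = 300, seed = 123)
  expect_lt(abs(null$mean_od - 26 / 3), 3 * null$se)
  # exchangeability: layer and column nulls agree within Monte-Carlo error
  null_c <- od_expectation_random(make_maze("pegboard"), "column",
                                  n_mc = 300, seed = 456)
  expect_lt(abs(null$mean_od - null_c$mean_od),
            3 * sqrt(null$se^2 + null_c$se^2))
})

test_that("no visit order beats the boustrophedon's layer+column OD sum on a toy grid", {
  # exhaustive check on a 3x3 grid: 8! anchored orders
  pb <- make_maze("pegboard")
  phys <- as.matrix(expand.grid(x = c(10, 30, 50), z = c(10, 30, 50)))
  colnames(phys) <- c("X", "Z")
  lay <- toy_layout(pb, phys, c(0L, 0L))
  bx <- lay$baited_grid[, 1]
  bz <- lay$baited_grid[, 2]
  # fast oracle: for 3 ordinals a<b<c the pairwise-distance mean is
  # 2(c-a)/3, so the per-axis OD is the band mean of that range term
  od_sum <- function(ordinals) {
    s <- 0
    for (bands in list(bx, bz)) {
      tot <- 0
      for (b in 0:2) {
        v <- ordinals[bands == b]
        tot <- tot + 2 * (max(v) - min(v)) / 3
      }
      s <- s + tot / 3
    }
    s
  }
  best <- Inf
  ordinals <- integer(9)
  for (tail in all_perms(2:9)) {
    ordinals[c(1L, tail)] <- 1:9
    s <- od_sum(ordinals)
    if (s < best) best <- s
  }
  # 3x3 row snake: layer OD 1, column OD (3+3+3+3+6+6)/ (3 bands * 3 pairs)
  snake <- toy_sequence(lay, c(1, 2, 3, 6, 5, 4, 7, 8, 9))
  snake_sum <- od_per_group(snake, "layer")$mean_od +
    od_per_group(snake, "column")$mean_od
  expect_equal(best, snake_sum)
})
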