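# Independent oracles and toy-layout builders used across the suite.

# All permutations of a vector (recursive; fine up to length 7-8).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Exhaustive shortest open route with a fixed first element.
brute_force_route <- function(layout, anchor) {
  n <- nrow(layout$baited_phys)
  d <- as.matrix(stats::dist(layout$baited_phys))
  best_len <- Inf
  best <- NULL
  for (tail in all_perms(setdiff(seq_len(n), anchor))) {
    ord <- c(anchor, tail)
    len <- sum(d[cbind(ord[-n], ord[-1])])
    if (len < best_len) { best_len <- len; best <- ord }
  }
  list(order = best, length = best_len)
}

# Direct double-loop ordinal distance (Eq-style brute force).
od_brute <- function(ordinals) {
  n <- length(ordinals)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + abs(ordinals[i] - ordinals[j])
  s / (n * (n - 1) / 2)
}

# Hand-built layout with explicit baited physical coordinates. Grid
# indices are derived by flooring coordinates into the maze's cells.
toy_layout <- function(maze, phys, start, trial_id = 1L) {
  phys <- as.matrix(phys)
  grid <- floor(sweep(phys, 2, maze$cell_size, `/`))
  grid <- pmin(pmax(grid, 0L), matrix(maze$grid_shape - 1L, nrow(grid),
                                      ncol(grid), byrow = TRUE))
  storage.mode(grid) <- "integer"
  dimnames(grid) <- list(NULL, maze$axis_names)
  dimnames(phys) <- list(NULL, maze$axis_names)
  structure(list(maze = maze, start = as.integer(start), baited_grid = grid,
                 baited_phys = phys, trial_id = trial_id, seed = NA_integer_),
            class = "food_layout")
}

# Visit sequence with an explicit order over a layout's baited rows.
toy_sequence <- function(layout, order, strategy = "manual") {
  structure(list(layout = layout, order = as.integer(order),
                 strategy = strategy),
            class = "visit_sequence")
}

# Boustrophedon visit order over the full pegboard (row-major snake),
# constructed independently of simulate_visits().
pegboard_snake_layout <- function(seed = 1) {
  pb <- make_maze("pegboard")
  lay <- generate_layout(pb, c(0L, 0L), seed = seed)
  # layout rows are expand.grid(x = 0:4, z = 0:4): x fastest
  idx <- integer(0)
  for (z in 0:4) {
    row <- which(lay$baited_grid[, 2] == z)
    row <- row[order(lay$baited_grid[row, 1])]
    if (z %% 2 == 1) row <- rev(row)
    idx <- c(idx, row)
  }
  toy_sequence(lay, idx, "snake")
}
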