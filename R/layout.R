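# Food-layout generation following the baiting protocols of the two
# foraging experiments. Randomness is local: the caller's RNG state is
# restored on exit whenever a seed is supplied.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate one trial's food layout
#'
#' Emulates the baiting protocols of the two foraging experiments.
#' Pegboard: all 25 reward regions are baited, the exact peg within each
#' region (one of the four pegs of the 2 x 2 array, i.e. an offset of
#' +/-5 cm per axis from the region centre) drawn uniformly per trial.
#' Lattice: 24 baited positions, exactly 6 drawn uniformly from the 25
#' (5 x 5) intersection points of each of the 4 layers. Intersection
#' coordinates are snapped to the nearest cube for grid-level analyses
#' (ties broken toward the lower index); the layer index is the cube
#' Z index by protocol.
#'
#' @param maze A [make_maze()] spec.
#' @param start_corner A corner grid position of the maze (0-based
#'   integer vector); see [maze_corners()].
#' @param trial_id Identifier carried through to output tables.
#' @param seed Integer seed; the layout is deterministic given the seed
#'   and the caller's RNG state is left untouched.
#' @return A `food_layout`: list with `maze`, `start` (grid position),
#'   `baited_grid` (n x d integer matrix of 0-based cell indices),
#'   `baited_phys` (n x d numeric matrix, cm), `trial_id`, `seed`.
#' @export
generate_layout <- function(maze, start_corner, trial_id = 1L, seed = NULL) {
  stopifnot(is_maze_spec(maze))
  start_corner <- as_grid_matrix(start_corner, maze)
  if (!is_corner(start_corner, maze)) {
    stop("start_corner must be one of the maze's corner positions", call. = FALSE)
  }
  with_seed(seed, {
    if (maze$name == "pegboard") {
      grid <- as.matrix(expand.grid(x = 0:4, z = 0:4))[, 1:2]
      storage.mode(grid) <- "integer"
      centres <- to_physical(grid, maze)
      # one of the 4 pegs per region: centre +/- 5 cm on each axis
      offs <- matrix(sample(c(-5, 5), 50, replace = TRUE), ncol = 2)
      phys <- centres + offs
    } else {
      per_layer <- lapply(0:3, function(lz) {
        pick <- sample.int(25L, 6L) - 1L          # 5 x 5 intersections
        ij <- cbind(pick %% 5L, pick %/% 5L)
        cbind(ij, lz)
      })
      ij <- do.call(rbind, per_layer)
      # intersections are at multiples of 12.5 cm; cube index = nearest
      # cube centre, ties toward the lower index
      snap <- function(i) pmax(i - 1L, 0L)
      grid <- cbind(snap(ij[, 1]), snap(ij[, 2]), ij[, 3])
      storage.mode(grid) <- "integer"
      phys <- cbind(ij[, 1] * 12.5, ij[, 2] * 12.5, (ij[, 3] + 0.5) * 12.5)
    }
    dimnames(grid) <- list(NULL, maze$axis_names)
    dimnames(phys) <- list(NULL, maze$axis_names)
    structure(
      list(maze = maze, start = start_corner[1, ], baited_grid = grid,
           baited_phys = phys, trial_id = trial_id, seed = seed),
      class = "food_layout"
    )
  })
}

#' @export
print.food_layout <- function(x, ...) {
  cat(sprintf("<food_layout> trial %s on %s: %d baited positions, start (%s)\n",
              x$trial_id, x$maze$name, nrow(x$baited_grid),
              paste(x$start, collapse = ",")))
  invisible(x)
}

n_baited <- function(layout) nrow(layout$baited_grid)

#' Write / read a food layout as CSV
#'
#' One row per baited position: trial id, axis indices and physical
#' coordinates, plus the start corner repeated for round-tripping.
#'
#' @param layout A `food_layout`.
#' @param path CSV file path.
#' @export
write_layout_csv <- function(layout, path) {
  d <- data.frame(trial_id = layout$trial_id, layout$baited_grid,
                  check.names = FALSE)
  phys <- layout$baited_phys
  colnames(phys) <- paste0(tolower(colnames(phys)), "_cm")
  d <- cbind(d, phys,
             start = paste(layout$start, collapse = ";"),
             maze = layout$maze$name)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @param path CSV file path written by [write_layout_csv()].
#' @export
read_layout_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  maze <- make_maze(d$maze[1])
  ax <- maze$axis_names
  grid <- as.matrix(d[, ax])
  storage.mode(grid) <- "integer"
  phys <- as.matrix(d[, paste0(tolower(ax), "_cm")])
  colnames(phys) <- ax
  start <- as.integer(strsplit(d$start[1], ";")[[1]])
  structure(
    list(maze = maze, start = start, baited_grid = grid, baited_phys = phys,
         trial_id = d$trial_id[1], seed = NA_integer_),
    class = "food_layout"
  )
}
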