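#' Construct a maze specification
#'
#' Defines one of the two climbing apparatuses as a discrete grid with
#' physical coordinates. The pegboard is a vertical board analysed as a
#' 5 x 5 grid of reward regions (20 cm pitch: 2 x 2 pegs at 10 cm spacing
#' per region) with one horizontal axis (X) and one vertical axis (Z).
#' The lattice maze is a 50 cm cube of 4 x 4 x 4 hollow cubes (12.5 cm
#' edge) with two horizontal axes (X, Y) and a vertical axis (Z). The
#' origin is the front lower-left corner; grid indices are 0-based.
#'
#' @param name `"pegboard"` or `"lattice"`.
#' @return A `maze_spec` object: a list with `name`, `n_dims`,
#'   `grid_shape`, `cell_size` (cm per axis), `axis_names`, and
#'   `vertical_axis` (the 1-based axis index flagged vertical).
#' @examples
#' make_maze("pegboard")$grid_shape   # 5 5
#' make_maze("lattice")$cell_size     # 12.5 12.5 12.5
#' @export
make_maze <- function(name = c("pegboard", "lattice")) {
  name <- match.arg(name)
  spec <- if (name == "pegboard") {
    list(
      name = "pegboard",
      n_dims = 2L,
      grid_shape = c(5L, 5L),
      cell_size = c(20, 20),
      axis_names = c("X", "Z"),
      vertical_axis = 2L
    )
  } else {
    list(
      name = "lattice",
      n_dims = 3L,
      grid_shape = c(4L, 4L, 4L),
      cell_size = c(12.5, 12.5, 12.5),
      axis_names = c("X", "Y", "Z"),
      vertical_axis = 3L
    )
  }
  structure(spec, class = "maze_spec")
}

#' @export
print.maze_spec <- function(x, ...) {
  cat(sprintf(
    "<maze_spec> %s: %s grid, cell size %s cm, axes %s (vertical: %s)\n",
    x$name, paste(x$grid_shape, collapse = " x "),
    paste(unique(x$cell_size), collapse = "/"),
    paste(x$axis_names, collapse = ","),
    x$axis_names[x$vertical_axis]
  ))
  invisible(x)
}

is_maze_spec <- function(x) inherits(x, "maze_spec")

#' Validate grid positions against a maze
#'
#' @param pos An integer matrix of 0-based grid indices, one row per
#'   position and one column per maze axis (a single position may be
#'   given as a vector).
#' @param maze A [make_maze()] spec.
#' @return The positions as an integer matrix, invisibly checked.
#' @keywords internal
as_grid_matrix <- function(pos, maze) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  pos <- as.matrix(pos)
  if (ncol(pos) != maze$n_dims) {
    stop(sprintf("positions must have %d columns for maze '%s'",
                 maze$n_dims, maze$name), call. = FALSE)
  }
  storage.mode(pos) <- "integer"
  bad <- pos < 0L | pos >= matrix(maze$grid_shape, nrow(pos), ncol(pos), byrow = TRUE)
  if (any(bad)) stop("grid position out of range for maze", call. = FALSE)
  pos
}

#' Band index of grid positions along a grouping axis
#'
#' Partitions the maze into bands: `layer` bands have constant height
#' (Z); pegboard `column` bands have constant X; lattice `slice_xz`
#' bands have constant Y and `slice_yz` bands constant X. Every grid
#' position belongs to exactly one band per mode.
#'
#' @inheritParams as_grid_matrix
#' @param mode One of `"layer"`, `"column"`, `"slice_xz"`, `"slice_yz"`.
#' @return Integer vector of 0-based band indices, one per position.
#' @examples
#' pb <- make_maze("pegboard")
#' group_of(c(3L, 0L), pb, "layer")   # 0
#' group_of(c(3L, 0L), pb, "column")  # 3
#' @export
group_of <- function(pos, maze, mode = c("layer", "column", "slice_xz", "slice_yz")) {
  mode <- match.arg(mode)
  pos <- as_grid_matrix(pos, maze)
  axis <- grouping_axis_index(maze, mode)
  as.integer(pos[, axis])
}

# Maps a grouping mode to the grid axis whose index identifies the band.
grouping_axis_index <- function(maze, mode) {
  if (maze$name == "pegboard") {
    switch(mode,
      layer = 2L,   # constant-Z rows
      column = 1L,  # constant-X strips
      stop(sprintf("mode '%s' is not defined for the pegboard", mode),
           call. = FALSE)
    )
  } else {
    switch(mode,
      layer = 3L,    # constant-Z horizontal planes
      slice_xz = 2L, # constant-Y vertical planes
      slice_yz = 1L, # constant-X vertical planes
      stop(sprintf("mode '%s' is not defined for the lattice", mode),
           call. = FALSE)
    )
  }
}

#' Grouping modes applicable to a maze
#'
#' @param maze A [make_maze()] spec.
#' @return Character vector of valid `group_of()` modes.
#' @export
maze_modes <- function(maze) {
  if (maze$name == "pegboard") c("layer", "column")
  else c("layer", "slice_xz", "slice_yz")
}

#' Physical cell-centre coordinates of grid positions
#'
#' @inheritParams as_grid_matrix
#' @return Numeric matrix of coordinates in cm: `(index + 0.5) * cell_size`.
#' @examples
#' to_physical(c(0L, 0L), make_maze("pegboard"))  # 10 10
#' @export
to_physical <- function(pos, maze) {
  pos <- as_grid_matrix(pos, maze)
  xy <- sweep(pos + 0.5, 2, maze$cell_size, `*`)
  dimnames(xy) <- list(NULL, maze$axis_names)
  xy
}

#' Corner grid positions of a maze
#'
#' @param maze A [make_maze()] spec.
#' @return Integer matrix with one corner per row (0-based indices),
#'   in row-major order of the corner pattern.
#' @export
maze_corners <- function(maze) {
  ext <- lapply(maze$grid_shape, function(s) c(0L, s - 1L))
  m <- as.matrix(expand.grid(ext))
  dimnames(m) <- list(NULL, maze$axis_names)
  m
}

is_corner <- function(pos, maze) {
  pos <- as_grid_matrix(pos, maze)
  all(pos == 0L | pos == maze$grid_shape - 1L)
}

#' Serialise / deserialise a maze spec as JSON
#'
#' @param maze A `maze_spec`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `maze_to_json()`: the JSON string (invisibly, if written to a
#'   file); `maze_from_json()`: a `maze_spec`.
#' @export
maze_to_json <- function(maze, path = NULL) {
  json <- jsonlite::toJSON(unclass(maze), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname maze_to_json
#' @param json JSON string or path to a JSON file.
#' @export
maze_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  spec <- make_maze(x$name)
  stopifnot(identical(spec$grid_shape, as.integer(x$grid_shape)))
  spec
}
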