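# Bin/cube crossing analysis: the movement-anisotropy measure. A
# crossing is a change of occupied grid cell along one axis; horizontal
# vs vertical crossing counts compare how movement is distributed
# between dimensions.

#' Map a trajectory to its bin sequence
#'
#' Each sample is assigned to the grid cell containing it (half-open
#' convention: `floor(coord / cell_size)`, so a point exactly on an
#' internal boundary belongs to the higher-index bin; points on the
#' outer edge are clamped into the grid). Consecutive duplicate bins are
#' collapsed. An optional running median filter of odd width can be
#' applied to the coordinates first.
#'
#' @param traj A [visits_to_trajectory()] result, or a list with `maze`
#'   and a `samples` data frame (`t` plus one column per axis, cm).
#' @param median_width Odd integer window for a running-median smooth of
#'   each coordinate before binning; `0` (default) disables smoothing.
#' @return Integer matrix of 0-based bin indices, one row per distinct
#'   successive bin.
#' @export
bin_trajectory <- function(traj, median_width = 0) {
  maze <- traj$maze
  coords <- as.matrix(traj$samples[, maze$axis_names, drop = FALSE])
  if (nrow(coords) == 0L) stop("empty trajectory", call. = FALSE)
  if (median_width > 0) {
    stopifnot(median_width %% 2 == 1)
    coords <- apply(coords, 2, stats::runmed, k = min(median_width, nrow(coords)))
    if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  }
  bins <- floor(sweep(coords, 2, maze$cell_size, `/`))
  bins <- pmin(sweep(bins, 2, maze$grid_shape - 1L, pmin), bins)  # clamp top edge
  bins <- pmax(bins, 0L)
  storage.mode(bins) <- "integer"
  keep <- if (nrow(bins) == 1L) TRUE
          else c(TRUE, rowSums(abs(diff(bins))) > 0)
  bins <- bins[keep, , drop = FALSE]
  dimnames(bins) <- list(NULL, maze$axis_names)
  bins
}

#' Count per-axis bin crossings of a bin sequence
#'
#' For every pair of consecutive bins, each axis accumulates the
#' absolute index change along that axis; a diagonal bin change
#' increments every changed axis.
#'
#' @param bins Integer matrix of bin indices (rows in temporal order),
#'   e.g. from [bin_trajectory()].
#' @return A `crossing_counts` list: `per_axis` (named integer vector)
#'   and `n_transitions` (number of consecutive bin changes).
#' @examples
#' count_crossings(rbind(c(0, 0), c(1, 0), c(1, 1)))$per_axis  # 1 1
#' @export
count_crossings <- function(bins) {
  bins <- as.matrix(bins)
  if (nrow(bins) < 1L) stop("need at least one bin", call. = FALSE)
  if (nrow(bins) == 1L) {
    per_axis <- stats::setNames(integer(ncol(bins)), colnames(bins))
    return(structure(list(per_axis = per_axis, n_transitions = 0L),
                     class = "crossing_counts"))
  }
  d <- abs(diff(bins))
  per_axis <- colSums(d)
  storage.mode(per_axis) <- "integer"
  structure(list(per_axis = per_axis,
                 n_transitions = sum(rowSums(d) > 0)),
            class = "crossing_counts")
}

#' @export
print.crossing_counts <- function(x, ...) {
  cat("<crossing_counts>",
      paste(sprintf("%s=%d", names(x$per_axis), x$per_axis), collapse = " "),
      sprintf("(%d transitions)\n", x$n_transitions))
  invisible(x)
}

#' Crossing counts of a retrieval route
#'
#' Applies the same crossing counting to a visit order: consecutive
#' retrieval positions are connected by the straight physical segment
#' between their cell centres, rasterised onto the bin grid. Because a
#' straight segment is monotone along every axis, the per-axis count
#' equals the summed absolute index change between consecutive
#' retrieval bins.
#'
#' @param x A `visit_sequence` or `route`.
#' @return A `crossing_counts` (see [count_crossings()]).
#' @export
crossings_for_route <- function(x) {
  grid <- x$layout$baited_grid[x$order, , drop = FALSE]
  count_crossings(rasterise_route(grid, x$layout$maze))
}

# Bin sequence of a polyline through cell centres: each straight segment
# is sampled below half the cell size so no intermediate bin is skipped.
rasterise_route <- function(grid, maze) {
  centres <- to_physical(grid, maze)
  if (nrow(centres) == 1L) return(grid)
  step <- min(maze$cell_size) / 4
  pts <- list(centres[1, , drop = FALSE])
  for (k in 2:nrow(centres)) {
    a <- centres[k - 1, ]; b <- centres[k, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    u <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))[-1]
    pts[[length(pts) + 1L]] <- t(vapply(u, function(f) a + f * (b - a),
                                        numeric(length(a))))
  }
  coords <- do.call(rbind, pts)
  samples <- data.frame(t = seq_len(nrow(coords)), coords, check.names = FALSE)
  colnames(samples) <- c("t", maze$axis_names)
  bin_trajectory(list(maze = maze, samples = samples))
}

#' Write / read a trajectory CSV
#'
#' Columns: `t` in seconds, then one physical coordinate per axis in cm.
#'
#' @param traj A `trajectory`.
#' @param path CSV file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param maze The maze the trajectory was recorded in.
#' @export
read_trajectory_csv <- function(path, maze) {
  samples <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(maze$axis_names %in% colnames(samples)))
  structure(list(maze = maze, samples = samples), class = "trajectory")
}
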