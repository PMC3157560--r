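# Synthetic foraging agents. Each strategy emits a visit order over the
# baited positions of a layout; all strategies anchor the first visit at
# the baited position nearest the start corner, so synthetic, observed
# and distance-optimised sequences remain comparable.

#' Simulate a visit order over a food layout
#'
#' Strategies:
#' \describe{
#'   \item{`layer_snake`}{exhausts each horizontal band (constant Z)
#'     before moving vertically, boustrophedon within a band, sweeping
#'     monotonically away from the start corner's band — the idealised
#'     "layer strategy".}
#'   \item{`column_snake`}{the transpose: exhausts constant-X bands,
#'     the idealised vertically biased strategy.}
#'   \item{`random_order`}{uniform permutation of the non-anchor
#'     positions.}
#'   \item{`greedy_nearest`}{nearest unvisited baited position by
#'     Euclidean distance over physical coordinates, ties broken toward
#'     the lower row-major linear grid index.}
#' }
#'
#' @param layout A [generate_layout()] result.
#' @param strategy Strategy name (see Details).
#' @param seed Integer seed for the stochastic strategies; deterministic
#'   strategies ignore it.
#' @return A `visit_sequence`: list with `layout`, `order` (indices into
#'   the layout's baited rows, visit order = ordinals 1..N), `strategy`.
#' @export
simulate_visits <- function(layout,
                            strategy = c("layer_snake", "column_snake",
                                         "random_order", "greedy_nearest"),
                            seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(layout, "food_layout"))
  maze <- layout$maze
  phys <- layout$baited_phys
  n <- nrow(phys)
  start_xy <- to_physical(layout$start, maze)[1, ]
  anchor <- which.min(colSums((t(phys) - start_xy)^2))

  order_idx <- switch(strategy,
    layer_snake = snake_order(layout, band_axis = maze$vertical_axis),
    column_snake = snake_order(layout, band_axis = 1L),
    random_order = with_seed(seed, c(anchor, sample(setdiff(seq_len(n), anchor)))),
    greedy_nearest = greedy_order(layout, anchor)
  )
  structure(list(layout = layout, order = order_idx, strategy = strategy),
            class = "visit_sequence")
}

# Boustrophedon sweep: bands along `band_axis` are visited monotonically
# starting from the start corner's band; within a band positions are
# serpentine-ordered over the remaining axes, orientation alternating so
# consecutive band end-points stay adjacent.
snake_order <- function(layout, band_axis) {
  maze <- layout$maze
  grid <- layout$baited_grid
  phys <- layout$baited_phys
  start <- layout$start
  bands <- sort(unique(grid[, band_axis]))
  if (start[band_axis] > 0L) bands <- rev(bands)

  other <- setdiff(seq_len(maze$n_dims), band_axis)
  out <- integer(0)
  prev <- to_physical(start, maze)[1, ]
  for (b in bands) {
    idx <- which(grid[, band_axis] == b)
    if (length(idx) == 0L) next
    if (length(other) == 1L) {
      o <- idx[order(phys[idx, other])]
    } else {
      # serpentine over (secondary, primary): rows of the secondary axis,
      # alternating direction along the primary axis
      a1 <- other[1]; a2 <- other[2]
      rows <- sort(unique(grid[idx, a2]))
      o <- integer(0)
      flip <- FALSE
      for (r in rows) {
        ridx <- idx[grid[idx, a2] == r]
        ridx <- ridx[order(phys[ridx, a1], decreasing = flip)]
        o <- c(o, ridx)
        flip <- !flip
      }
    }
    # orient the band so its first element is nearest the previous point
    d_head <- sum((phys[o[1], ] - prev)^2)
    d_tail <- sum((phys[o[length(o)], ] - prev)^2)
    if (d_tail < d_head) o <- rev(o)
    out <- c(out, o)
    prev <- phys[o[length(o)], ]
  }
  out
}

greedy_order <- function(layout, anchor) {
  phys <- layout$baited_phys
  grid <- layout$baited_grid
  shape <- layout$maze$grid_shape
  # row-major linear index used as the deterministic tie-break
  lin <- as.vector(grid %*% cumprod(c(1, shape[-length(shape)])))
  n <- nrow(phys)
  visited <- logical(n)
  out <- integer(n)
  out[1] <- anchor
  visited[anchor] <- TRUE
  for (k in 2:n) {
    cur <- phys[out[k - 1], ]
    d <- colSums((t(phys) - cur)^2)
    d[visited] <- Inf
    cand <- which(d == min(d))
    out[k] <- cand[order(lin[cand])][1]
    visited[out[k]] <- TRUE
  }
  out
}

#' @export
print.visit_sequence <- function(x, ...) {
  cat(sprintf("<visit_sequence> %s, %d visits on %s (trial %s)\n",
              x$strategy, length(x$order), x$layout$maze$name,
              x$layout$trial_id))
  invisible(x)
}

#' Visit sequence as a data frame
#'
#' @param x A `visit_sequence`.
#' @param ... Unused.
#' @return Data frame with `ordinal` (1..N), grid indices and physical
#'   coordinates in visit order.
#' @export
as.data.frame.visit_sequence <- function(x, ...) {
  grid <- x$layout$baited_grid[x$order, , drop = FALSE]
  phys <- x$layout$baited_phys[x$order, , drop = FALSE]
  colnames(phys) <- paste0(tolower(colnames(phys)), "_cm")
  data.frame(trial_id = x$layout$trial_id, ordinal = seq_along(x$order),
             grid, phys, check.names = FALSE)
}

#' Constant-speed trajectory through a visit sequence
#'
#' Stands in for the position-tracking output: a piecewise-linear path
#' through the physical coordinates of the visit order, sampled at a
#' fixed rate assuming constant speed.
#'
#' @param seq A [simulate_visits()] result (or a `route`).
#' @param sampling_rate Samples per second (Hz), > 0.
#' @param speed Travel speed in cm/s, > 0.
#' @return A `trajectory`: list with `maze` and `samples`, a data frame
#'   of `t` (s) and one physical coordinate column per axis (cm).
#' @export
visits_to_trajectory <- function(seq, sampling_rate = 10, speed = 10) {
  stopifnot(sampling_rate > 0, speed > 0)
  phys <- seq$layout$baited_phys[seq$order, , drop = FALSE]
  maze <- seq$layout$maze
  if (nrow(phys) == 1L) {
    samples <- data.frame(t = 0, phys, check.names = FALSE)
    return(structure(list(maze = maze, samples = samples), class = "trajectory"))
  }
  seg <- sqrt(rowSums(diff(phys)^2))
  cum <- c(0, cumsum(seg))
  total_t <- cum[length(cum)] / speed
  t <- (0:floor(total_t * sampling_rate + 1e-9)) / sampling_rate
  if (t[length(t)] < total_t - 1e-9) t <- c(t, total_t)
  s <- t * speed
  coords <- vapply(seq_len(ncol(phys)),
                   function(a) stats::approx(cum, phys[, a], xout = s,
                                             ties = "ordered")$y,
                   numeric(length(s)))
  colnames(coords) <- maze$axis_names
  structure(list(maze = maze,
                 samples = data.frame(t = t, coords, check.names = FALSE)),
            class = "trajectory")
}

#' Simulate detour route-choice records
#'
#' Bernoulli choice model for the barrier detour tasks: per direction of
#' travel, each rat chooses the horizontal-first route with a fixed
#' probability, independently across trials.
#'
#' @param p_horizontal_first Named probability vector, one entry per
#'   direction condition (e.g. `c(up = 0.95, down = 0.4)`).
#' @param n_rats Number of rats.
#' @param n_trials_per_rat Trials per rat and direction.
#' @param seed Integer seed; records are deterministic given the seed.
#' @return Data frame with `rat`, `trial`, `direction`, `choice`
#'   (`"horizontal_first"` / `"vertical_first"`).
#' @export
simulate_detours <- function(p_horizontal_first, n_rats = 6L,
                             n_trials_per_rat = 10L, seed = NULL) {
  stopifnot(all(p_horizontal_first >= 0 & p_horizontal_first <= 1),
            n_rats >= 1, n_trials_per_rat >= 1)
  if (is.null(names(p_horizontal_first))) {
    names(p_horizontal_first) <- if (length(p_horizontal_first) == 1) "up"
      else paste0("dir", seq_along(p_horizontal_first))
  }
  with_seed(seed, {
    recs <- lapply(names(p_horizontal_first), function(dir) {
      p <- p_horizontal_first[[dir]]
      data.frame(
        rat = rep(seq_len(n_rats), each = n_trials_per_rat),
        trial = rep(seq_len(n_trials_per_rat), times = n_rats),
        direction = dir,
        choice = ifelse(stats::runif(n_rats * n_trials_per_rat) < p,
                        "horizontal_first", "vertical_first")
      )
    })
    do.call(rbind, recs)
  })
}
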