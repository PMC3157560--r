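# Ordinal-distance (OD) statistic: the central measure of how strongly
# retrieval order clusters within bands of the maze. Each food location
# carries an ordinal number 1..N (its rank in the visit order); the OD
# of a band is the mean absolute difference over all ordinal pairs in
# that band, and the summary OD averages bands holding >= 2 ordinals.
# Low layer OD relative to column/slice OD indicates a horizontally
# organised, layer-by-layer foraging strategy.

#' Per-band ordinal distances of a visit sequence
#'
#' For band k along the grouping axis, with ordinals \eqn{x_1..x_n}
#' (n >= 2) of the food retrieved in that band,
#' \deqn{OD_k = \sum_{i<j} |x_i - x_j| / (n(n-1)/2),}
#' and the summary \eqn{OD = \sum_k OD_k / p} over the p bands with
#' n >= 2; bands with fewer than 2 retrievals are excluded.
#'
#' @param seq A `visit_sequence` or `route` (any object carrying a
#'   `layout` and a visit `order`).
#' @param mode Grouping mode, see [group_of()].
#' @return An `od_result`: list with `mode`, `per_group` (data frame of
#'   `group`, `od`, `n`), `mean_od`, `p`.
#' @examples
#' pb <- make_maze("pegboard")
#' lay <- generate_layout(pb, c(0L, 0L), seed = 1)
#' snake <- simulate_visits(lay, "layer_snake")
#' od_per_group(snake, "layer")$mean_od   # 2.0
#' @export
od_per_group <- function(seq, mode) {
  layout <- seq$layout
  grid <- layout$baited_grid[seq$order, , drop = FALSE]
  ordinals <- seq_along(seq$order)
  bands <- group_of(grid, layout$maze, mode)
  od_from_ordinals(ordinals, bands, mode)
}

# Core OD computation on (ordinal, band) pairs.
od_from_ordinals <- function(ordinals, bands, mode) {
  stopifnot(length(ordinals) == length(bands),
            !anyDuplicated(ordinals))
  per <- lapply(sort(unique(bands)), function(k) {
    x <- ordinals[bands == k]
    if (length(x) < 2L) return(NULL)
    data.frame(group = k, od = mean(stats::dist(x)), n = length(x))
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L) {
    stop("no band holds two or more retrieved positions (p = 0)", call. = FALSE)
  }
  structure(list(mode = mode, per_group = per,
                 mean_od = mean(per$od), p = nrow(per)),
            class = "od_result")
}

#' @export
print.od_result <- function(x, ...) {
  cat(sprintf("<od_result> mode %s: mean OD %.3f over %d bands\n",
              x$mode, x$mean_od, x$p))
  invisible(x)
}

#' Ordinal-distance ratio of an observed against an optimised sequence
#'
#' The observed mean OD divided by the mean OD of the distance-optimal
#' reference route on the same layout and grouping axis. A layer ratio
#' below 1 indicates horizontal clustering beyond what pure distance
#' optimisation produces.
#'
#' @param observed,optimised `od_result` objects on the same mode.
#' @return An `od_ratio`: list with `mode`, `observed_od`,
#'   `optimised_od`, `ratio`.
#' @export
od_ratio <- function(observed, optimised) {
  stopifnot(inherits(observed, "od_result"), inherits(optimised, "od_result"))
  if (!identical(observed$mode, optimised$mode)) {
    stop("observed and optimised ODs must use the same grouping mode",
         call. = FALSE)
  }
  if (optimised$mean_od <= 0) stop("optimised mean OD must be > 0", call. = FALSE)
  structure(list(mode = observed$mode,
                 observed_od = observed$mean_od,
                 optimised_od = optimised$mean_od,
                 ratio = observed$mean_od / optimised$mean_od),
            class = "od_ratio")
}

#' @export
print.od_ratio <- function(x, ...) {
  cat(sprintf("<od_ratio> mode %s: %.3f / %.3f = %.3f\n",
              x$mode, x$observed_od, x$optimised_od, x$ratio))
  invisible(x)
}

#' Monte-Carlo expectation of the OD under uniformly random visit orders
#'
#' The null reference: mean summary OD over `n_mc` uniformly random
#' permutations of fresh layouts. For distinct uniform ordinals on 1..N
#' the expected pairwise distance is (N+1)/3 (26/3 on the pegboard), the
#' same for every grouping axis by exchangeability.
#'
#' @param maze A [make_maze()] spec.
#' @param mode Grouping mode.
#' @param n_mc Number of Monte-Carlo replicates (>= 1).
#' @param seed Integer seed.
#' @return List with `mean_od`, `se` (Monte-Carlo standard error), and
#'   `n_mc`.
#' @export
od_expectation_random <- function(maze, mode, n_mc = 200L, seed = NULL) {
  stopifnot(n_mc >= 1)
  corner <- maze_corners(maze)[1, ]
  with_seed(seed, {
    vals <- vapply(seq_len(n_mc), function(i) {
      lay <- generate_layout(maze, corner, trial_id = i)
      n <- n_baited(lay)
      seq <- structure(list(layout = lay, order = sample.int(n),
                            strategy = "random_order"),
                       class = "visit_sequence")
      od_per_group(seq, mode)$mean_od
    }, numeric(1))
    list(mean_od = mean(vals),
         se = stats::sd(vals) / sqrt(n_mc),
         n_mc = n_mc)
  })
}

#' Per-trial OD table
#'
#' Convenience: the per-band ODs of one sequence over every grouping
#' mode valid for its maze, as a tidy data frame.
#'
#' @param seq A `visit_sequence` or `route`.
#' @return Data frame with `trial_id`, `mode`, `group`, `od`, `n`,
#'   `mean_od`, `p`.
#' @export
od_table <- function(seq) {
  modes <- maze_modes(seq$layout$maze)
  do.call(rbind, lapply(modes, function(m) {
    r <- od_per_group(seq, m)
    cbind(trial_id = seq$layout$trial_id, mode = m, r$per_group,
          mean_od = r$mean_od, p = r$p)
  }))
}
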