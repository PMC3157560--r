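# Distance-optimal reference routes. A mutation-only genetic algorithm
# searches for the shortest open path through a trial's baited
# positions, anchored at the food position adjacent to the start on the
# X axis. Because the objective is pure Euclidean distance in an
# isotropic space, the resulting routes carry no horizontal/vertical
# bias and serve as the gravity-blind control against which observed
# visit orders are compared.

#' Genetic-algorithm configuration
#'
#' Population of random routes; each generation the population is
#' randomly partitioned into groups, the shortest route of each group
#' survives and spawns one offspring per mutation operator (swap two
#' positions, flip a contiguous segment, slide a segment by one). The
#' search restarts from scratch `n_restarts` times and the overall
#' incumbent best is returned.
#'
#' The default profile (20 restarts x 2000 generations) converges on
#' 24-25 position instances; `ga_config(n_generations = 10000,
#' n_restarts = 1000)` gives the exhaustive search profile.
#'
#' @param population_size Routes per generation (divisible by
#'   `group_size`).
#' @param group_size Tournament group size; must equal
#'   `1 + n_mutants_per_survivor`.
#' @param n_mutants_per_survivor Offspring per surviving route.
#' @param n_generations Generations per restart.
#' @param n_restarts Independent restarts.
#' @param seed Optional integer seed (applied by [evolve()]).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, group_size = 4L,
                      n_mutants_per_survivor = 3L,
                      n_generations = 2000L, n_restarts = 20L,
                      seed = NULL) {
  stopifnot(population_size %% group_size == 0,
            group_size == 1L + n_mutants_per_survivor,
            n_generations >= 1, n_restarts >= 1)
  structure(list(population_size = as.integer(population_size),
                 group_size = as.integer(group_size),
                 n_mutants_per_survivor = as.integer(n_mutants_per_survivor),
                 n_generations = as.integer(n_generations),
                 n_restarts = as.integer(n_restarts),
                 seed = seed,
                 distance_metric = "euclidean"),
            class = "ga_config")
}

#' Total Euclidean length of an open route
#'
#' @param order Integer vector: a permutation of `1:n_baited(layout)`
#'   giving the visit order (indices into the layout's baited rows).
#' @param layout A `food_layout`.
#' @return Path length in cm (open path; no return to start).
#' @export
route_length <- function(order, layout) {
  n <- n_baited(layout)
  if (length(order) != n || !setequal(order, seq_len(n))) {
    stop("order must be a permutation of the layout's baited positions",
         call. = FALSE)
  }
  phys <- layout$baited_phys[order, , drop = FALSE]
  if (nrow(phys) < 2L) return(0)
  sum(sqrt(rowSums(diff(phys)^2)))
}

#' Index of the anchored first retrieval position
#'
#' The first retrieval position of a reference route is the food
#' position adjacent to the start on the X axis: the baited position
#' nearest (Euclidean, physical coordinates) to the centre of the grid
#' cell one X step inward from the start corner at equal height.
#'
#' @param layout A `food_layout`.
#' @return Integer row index into the layout's baited positions.
#' @export
anchor_index <- function(layout) {
  maze <- layout$maze
  target <- layout$start
  target[1] <- target[1] + if (target[1] == 0L) 1L else -1L
  centre <- to_physical(target, maze)[1, ]
  which.min(colSums((t(layout$baited_phys) - centre)^2))
}

#' Evolve a distance-optimal route for one layout
#'
#' @param layout A `food_layout` with at least 2 baited positions.
#' @param cfg A [ga_config()].
#' @return A `route`: list with `layout`, `order` (visit order, first
#'   element anchored), `length` (cm), `restart_best` (best length per
#'   restart).
#' @export
evolve <- function(layout, cfg = ga_config()) {
  stopifnot(inherits(layout, "food_layout"), inherits(cfg, "ga_config"))
  n <- n_baited(layout)
  if (n < 2L) stop("need at least 2 baited positions", call. = FALSE)
  anchor <- anchor_index(layout)
  dmat <- as.matrix(stats::dist(layout$baited_phys))
  run <- function() {
    ga_evolve_cpp(dmat, anchor - 1L, cfg$population_size, cfg$group_size,
                  cfg$n_generations, cfg$n_restarts)
  }
  res <- if (is.null(cfg$seed)) run() else with_seed(cfg$seed, run())
  structure(list(layout = layout, order = res$order + 1L,
                 length = res$length, restart_best = res$restart_best),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("<route> %d positions on %s, length %.1f cm\n",
              length(x$order), x$layout$maze$name, x$length))
  invisible(x)
}

#' Pooled optimised-control reference over many layouts
#'
#' Runs the genetic algorithm on each layout and pools the resulting
#' best routes' ordinal distances (per grouping mode) and per-axis
#' crossing counts as mean +/- SEM across layouts — the gravity-blind
#' control summaries.
#'
#' @param layouts List of `food_layout` objects (same maze).
#' @param cfg A [ga_config()]. If `cfg$seed` is set, layout i uses seed
#'   `cfg$seed + i` so runs are independent but reproducible.
#' @param modes Grouping modes to evaluate (default: all modes of the
#'   maze).
#' @return List with `routes`, `per_trial` (data frame: trial, mode,
#'   mean OD; plus crossing columns per axis), `od_summary` and
#'   `crossing_summary` (mean, sem, n).
#' @export
optimised_reference <- function(layouts, cfg = ga_config(), modes = NULL) {
  stopifnot(length(layouts) >= 1)
  maze <- layouts[[1]]$maze
  if (is.null(modes)) modes <- maze_modes(maze)
  routes <- vector("list", length(layouts))
  for (i in seq_along(layouts)) {
    cfg_i <- cfg
    if (!is.null(cfg$seed)) cfg_i$seed <- cfg$seed + i
    routes[[i]] <- evolve(layouts[[i]], cfg_i)
  }
  od <- do.call(rbind, lapply(seq_along(routes), function(i) {
    vals <- vapply(modes, function(m) od_per_group(routes[[i]], m)$mean_od,
                   numeric(1))
    data.frame(trial = layouts[[i]]$trial_id, mode = modes, mean_od = vals,
               row.names = NULL)
  }))
  cross <- do.call(rbind, lapply(seq_along(routes), function(i) {
    cc <- crossings_for_route(routes[[i]])$per_axis
    data.frame(trial = layouts[[i]]$trial_id, axis = names(cc),
               crossings = as.numeric(cc), row.names = NULL)
  }))
  od_summary <- aggregate_mean_sem(od$mean_od, od$mode)
  names(od_summary)[1] <- "mode"
  crossing_summary <- aggregate_mean_sem(cross$crossings, cross$axis)
  names(crossing_summary)[1] <- "axis"
  list(routes = routes, per_trial_od = od, per_trial_crossings = cross,
       od_summary = od_summary, crossing_summary = crossing_summary)
}

aggregate_mean_sem <- function(values, group) {
  g <- factor(group, levels = unique(group))
  data.frame(group = levels(g),
             mean = as.numeric(tapply(values, g, mean)),
             sem = as.numeric(tapply(values, g, function(v)
               stats::sd(v) / sqrt(length(v)))),
             n = as.integer(table(g)),
             row.names = NULL)
}
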