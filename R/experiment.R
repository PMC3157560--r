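# End-to-end orchestration: generate layouts -> simulate agents ->
# optimise reference routes -> ordinal-distance and crossing analyses
# -> summary tables, all derived from one master seed (child seed of
# trial i = master seed + i) and written as CSV with a JSON manifest.

#' Run a full synthetic foraging experiment
#'
#' @param maze_name `"pegboard"` or `"lattice"`.
#' @param n_trials Number of trials (>= 1); start corners are assigned
#'   round-robin over `start_corners`.
#' @param strategy Agent strategy passed to [simulate_visits()].
#' @param seed Master integer seed; trial i derives layout seed
#'   `seed + i`, agent seed `seed + 500000 + i` and GA seed
#'   `seed + 1000000 + i`.
#' @param ga A [ga_config()] (its `seed` field is overridden per trial).
#' @param start_corners Integer matrix of corner positions (one per
#'   row); default: corners balanced as in the foraging protocols
#'   (all four pegboard corners; bottom and top corner on the lattice).
#' @param out_dir Output directory; created if missing. `NULL` skips
#'   writing and returns tables only.
#' @return Invisibly, a list with `layouts`, `visits`, `routes`,
#'   `od` (per trial/mode observed and optimised mean ODs and ratios),
#'   `crossings` (observed and optimised per axis), `summary` tables,
#'   and `manifest`.
#' @export
run_experiment <- function(maze_name = "pegboard", n_trials = 8L,
                           strategy = "random_order", seed = 1L,
                           ga = ga_config(), start_corners = NULL,
                           out_dir = NULL) {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  maze <- make_maze(maze_name)
  if (is.null(start_corners)) {
    start_corners <- default_start_corners(maze)
  }
  corners <- start_corners[((seq_len(n_trials) - 1L) %% nrow(start_corners)) + 1L,
                           , drop = FALSE]

  layouts <- lapply(seq_len(n_trials), function(i) {
    generate_layout(maze, corners[i, ], trial_id = i, seed = seed + i)
  })
  visits <- lapply(seq_len(n_trials), function(i) {
    simulate_visits(layouts[[i]], strategy, seed = seed + 500000L + i)
  })
  routes <- lapply(seq_len(n_trials), function(i) {
    cfg <- ga
    cfg$seed <- seed + 1000000L + i
    evolve(layouts[[i]], cfg)
  })

  modes <- maze_modes(maze)
  od <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    do.call(rbind, lapply(modes, function(m) {
      obs <- od_per_group(visits[[i]], m)
      opt <- od_per_group(routes[[i]], m)
      data.frame(trial = i, mode = m, observed_od = obs$mean_od,
                 optimised_od = opt$mean_od,
                 ratio = od_ratio(obs, opt)$ratio)
    }))
  }))
  crossings <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    obs <- count_crossings(bin_trajectory(visits_to_trajectory(visits[[i]])))
    opt <- crossings_for_route(routes[[i]])
    rbind(
      data.frame(trial = i, data_type = "observed",
                 axis = names(obs$per_axis),
                 crossings = as.numeric(obs$per_axis)),
      data.frame(trial = i, data_type = "optimised",
                 axis = names(opt$per_axis),
                 crossings = as.numeric(opt$per_axis))
    )
  }))

  summary <- list(
    od = summary_table(od$observed_od, od$mode),
    od_optimised = summary_table(od$optimised_od, od$mode),
    ratio = summary_table(od$ratio, od$mode),
    crossings = summary_table(crossings$crossings,
                              paste(crossings$data_type, crossings$axis))
  )

  manifest <- list(maze = maze_name, n_trials = n_trials,
                   strategy = strategy, seed = seed,
                   ga = unclass(ga)[c("population_size", "group_size",
                                      "n_generations", "n_restarts")])
  result <- list(layouts = layouts, visits = visits, routes = routes,
                 od = od, crossings = crossings, summary = summary,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    write_experiment(result, out_dir)
  }
  invisible(result)
}

default_start_corners <- function(maze) {
  if (maze$name == "pegboard") {
    maze_corners(maze)  # all four corners, as in the foraging protocol
  } else {
    rbind(c(0L, 0L, 0L), c(0L, 0L, 3L))  # bottom and top start
  }
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(do.call(rbind, lapply(result$visits, as.data.frame)), "visit_sequences.csv")
  wr(do.call(rbind, lapply(result$routes, function(r) {
    d <- as.data.frame(structure(list(layout = r$layout, order = r$order,
                                      strategy = "optimised"),
                                 class = "visit_sequence"))
    d$route_length_cm <- r$length
    d
  })), "optimised_routes.csv")
  wr(result$od, "ordinal_distances.csv")
  wr(result$crossings, "crossings.csv")
  for (nm in names(result$summary)) {
    wr(result$summary[[nm]], paste0("summary_", nm, ".csv"))
  }
  manifest <- result$manifest
  manifest$files <- lapply(stats::setNames(paths, basename(paths)),
                           function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
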