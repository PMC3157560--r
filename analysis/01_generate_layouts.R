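#!/usr/bin/env Rscript
# Step 1: generate the synthetic trial layouts for both apparatuses.
#
# Pegboard trials bait all 25 reward regions (one of the four pegs per
# region, varying across trials); lattice trials bait 24 intersection
# positions, 6 per layer. Start corners are balanced across trials as
# in the foraging protocols. Everything downstream reads these CSVs.

library(forage3d)

seed <- 20260929L
n_trials <- 40L
out <- "results/layouts"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pb <- make_maze("pegboard")
pb_corners <- maze_corners(pb)
for (i in seq_len(n_trials)) {
  lay <- generate_layout(pb, pb_corners[((i - 1) %% 4) + 1, ],
                         trial_id = i, seed = seed + i)
  write_layout_csv(lay, file.path(out, sprintf("pegboard_%02d.csv", i)))
}

lt <- make_maze("lattice")
lt_starts <- rbind(c(0L, 0L, 0L), c(0L, 0L, 3L))
for (i in seq_len(n_trials)) {
  lay <- generate_layout(lt, lt_starts[((i - 1) %% 2) + 1, ],
                         trial_id = i, seed = seed + 1000L + i)
  write_layout_csv(lay, file.path(out, sprintf("lattice_%02d.csv", i)))
}

jsonlite::write_json(
  list(seed = seed, n_trials = n_trials,
       pegboard_seed_offset = 1L, lattice_seed_offset = 1001L),
  file.path(out, "seeds.json"), auto_unbox = TRUE)

cat(sprintf("wrote %d pegboard and %d lattice layouts to %s\n",
            n_trials, n_trials, out))
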