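#!/usr/bin/env Rscript
# Step 5: assemble the pooled results into one markdown report.

library(forage3d)

out <- "results/report.md"
lines <- c("# Movement anisotropy: synthetic foraging and detour analysis", "")

section <- function(title) lines <<- c(lines, paste("##", title), "")
tablemd <- function(d) {
  d[] <- lapply(d, function(x) if (is.numeric(x)) round(x, 3) else x)
  c(paste("|", paste(names(d), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|"),
    apply(d, 1, function(r) paste("|", paste(r, collapse = " | "), "|")),
    "")
}

section("Optimised (gravity-blind) controls")
for (maze in c("pegboard", "lattice")) {
  f <- sprintf("results/optimised_od_summary_%s.csv", maze)
  if (!file.exists(f)) next
  lines <- c(lines, paste0("Ordinal distances, ", maze, ":"), "",
             tablemd(read.csv(f)))
  lines <- c(lines, paste0("Crossings per axis, ", maze, ":"), "",
             tablemd(read.csv(sprintf("results/optimised_crossings_%s.csv", maze))))
}

section("Strategy OD ratios (observed / optimised)")
for (maze in c("pegboard", "lattice")) {
  f <- sprintf("results/strategy_od_%s.csv", maze)
  if (!file.exists(f)) next
  tab <- read.csv(f)
  agg <- aggregate(ratio ~ strategy + mode, tab, mean)
  wide <- reshape(agg, idvar = "strategy", timevar = "mode", direction = "wide")
  names(wide) <- sub("ratio\\.", "", names(wide))
  lines <- c(lines, paste0(maze, ":"), "", tablemd(wide))
}

section("Detour choices")
f <- "results/detour_summary.csv"
if (file.exists(f)) lines <- c(lines, tablemd(read.csv(f)))

writeLines(lines, out)
cat("wrote", out, "\n")
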