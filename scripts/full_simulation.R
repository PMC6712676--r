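#!/usr/bin/env Rscript
# Full factorial simulation sweep (offered as a script, deliberately not a
# test: the complete grid is hours of compute).  Crosses the documented
# scenario factors and writes one CSV row per (scenario, d) point.
#
#   Rscript scripts/full_simulation.R --reps 2000 --seed 1 --out scratch/full_sim.csv

suppressPackageStartupMessages(library(equivProfiles))
suppressPackageStartupMessages(library(optparse))

opt <- parse_args(OptionParser(option_list = list(
  make_option("--reps", type = "integer", default = 2000L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--s", type = "character", default = "10,50,100"),
  make_option("--out", type = "character", default = "scratch/full_sim.csv"))))

sizes <- list(c(100, 100), c(200, 200), c(300, 100), c(300, 300),
              c(400, 200), c(1000, 1000), c(1500, 500))
n0_frac <- c(0.10, 0.20, 0.50)
s_vals <- as.integer(strsplit(opt$s, ",")[[1]])
deltas <- c(0.025, 0.25, 1.25)

dir.create(dirname(opt$out), showWarnings = FALSE, recursive = TRUE)
rows <- list()
for (nm in sizes) for (f in n0_frac) for (s in s_vals) for (delta in deltas) {
  sc <- scenario(nm[1], nm[2], round(f * min(nm)), s = s, k = 3,
                 theta0 = 0.5, delta = delta, alpha = 0.05,
                 reps = opt$reps, seed = opt$seed)
  dmax <- scenario_distance(1 - 1e-9, sc)
  if (delta >= dmax) next  # limit unattainable in this universe
  grid <- unique(pmin(c(delta / 5, delta / 2, delta, 1.2 * delta, 2 * delta),
                      0.95 * dmax))
  pc <- power_curve(sc, grid)
  pc$n <- nm[1]; pc$m <- nm[2]; pc$n0 <- sc$n0; pc$s <- s; pc$delta <- delta
  rows[[length(rows) + 1L]] <- pc
  message(sprintf("done n=%d m=%d n0=%d s=%d delta=%g", nm[1], nm[2],
                  sc$n0, s, delta))
}
utils::write.csv(do.call(rbind, rows), opt$out, row.names = FALSE)
message("wrote ", opt$out)
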