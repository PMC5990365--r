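#!/usr/bin/env Rscript
# Polar maps of the direction-dependent effective endpoint mass at the two
# lateral hit positions (and the frontal one), the anisotropy that makes the
# right-court paddle feel heavier than the left-court paddle.

library(eventmass)
dir.create("results", showWarnings = FALSE)

p <- default_linkage()
rows <- list()
for (group in c("LP_R", "LP_L", "FP")) {
  geo <- group_geometry(group)
  q <- inverse_kinematics(p, geo$court_centre)
  prof <- effective_mass_polar(p, q, n_directions = 72)
  prof$group <- group
  rows[[group]] <- prof
  lateral <- effective_mass(p, q, 0)
  frontal <- effective_mass(p, q, pi / 2)
  cat(sprintf(
    "%s hit position (%+.3f, %.3f): lateral %.3f kg, frontal %.3f kg, range [%.3f, %.3f] kg\n",
    group, geo$court_centre[1], geo$court_centre[2], lateral, frontal,
    min(prof$mass_kg), max(prof$mass_kg)))
}
polar <- do.call(rbind, rows)
write.csv(polar[, c("group", "angle_rad", "mass_kg")],
          "results/effective_mass_polar.csv", row.names = FALSE)
cat("wrote results/effective_mass_polar.csv\n")
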