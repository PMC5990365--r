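#!/usr/bin/env Rscript
# Calibrate the stand-in manipulandum so the effective endpoint mass along
# the lateral hit direction is 1.5 kg at the right-court hit position and
# 1.0 kg at the left-court hit position, then compare with the frozen
# package defaults.

library(eventmass)
dir.create("results", showWarnings = FALSE)

cal <- calibrate_linkage(base_linkage())
g <- default_geometry()

cat("Calibration from the uncalibrated base parameter set:\n")
cat(sprintf("  body midline (robot frame): x_mid = %+.4f m (frozen %+.4f)\n",
            cal$x_mid, g$x_mid))
cat(sprintf("  court distance:             y0   = %.4f m (frozen %.4f)\n",
            cal$y0, g$y0))
cat(sprintf("  common mass scale:          %.4f\n", cal$mass_scale))
cat(sprintf("  achieved masses: right %.6f kg, left %.6f kg (residual %.2e kg)\n",
            cal$mass_right, cal$mass_left, cal$residual))

write.csv(data.frame(
  quantity = c("x_mid_m", "y0_m", "mass_scale", "mass_right_kg",
               "mass_left_kg", "residual_kg"),
  value = c(cal$x_mid, cal$y0, cal$mass_scale, cal$mass_right,
            cal$mass_left, cal$residual)
), "results/linkage_calibration.csv", row.names = FALSE)

write_linkage_config(cal$params, "results/linkage_calibrated.cfg")
cat("wrote results/linkage_calibration.csv and results/linkage_calibrated.cfg\n")
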