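#!/usr/bin/env Rscript
# Detect apical filopodia as LoG spots on synthetic ICAM-1 fields, exclude
# junctional signal via the junction mask, and report filopodia/um^2
# against the planted density at three density levels.

suppressMessages(library(temsig))
dir.create("results", showWarnings = FALSE)

quality_threshold <- 0.25
report <- do.call(rbind, lapply(c(0.001, 0.005, 0.02), function(dens) {
  f <- gen_filopodia_field(field_um = c(200, 200), density_per_um2 = dens,
                           junction_lines = TRUE, seed = 7)
  spots <- detect_spots(f$image, f$pixel_size_um)
  jm <- junction_mask_from_channel(1 * f$junction_mask, 0.5,
                                   dilation_um = 0.5,
                                   pixel_size_um = f$pixel_size_um)
  kept <- filter_spots(spots, quality_threshold, junction_mask = jm)
  est <- spot_density(kept, f$area_um2)
  planted_free <- sum(!f$spots$on_junction) / f$area_um2
  data.frame(planted_density = dens,
             planted_free_density = planted_free,
             estimated_density = est$density,
             n_detected = est$n_spots,
             removed_junction = attr(kept, "removed_junction"))
}))
write.csv(report, "results/filopodia_density.csv", row.names = FALSE)
print(report, row.names = FALSE)
message(sprintf(
  "max relative error vs planted off-junction density: %.1f%%",
  100 * max(abs(report$estimated_density / report$planted_free_density - 1))))

# spot table for the middle density, for inspection
f <- gen_filopodia_field(field_um = c(200, 200), density_per_um2 = 0.005,
                         seed = 7)
kept <- filter_spots(detect_spots(f$image, f$pixel_size_um),
                     quality_threshold,
                     junction_mask = junction_mask_from_channel(
                       1 * f$junction_mask, 0.5, 0.5, f$pixel_size_um))
write.csv(kept, "results/spots.csv", row.names = FALSE)
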