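#!/usr/bin/env Rscript
# Two-wave spatial statistics: signed nearest-neighbour distances of
# second-wave neutrophils (and matched random dots) to first-wave surfaces,
# at zero attraction (null calibration) and at 0.8 attraction (hotspot
# reuse); plus adhesion counts / diapedesis efficacy and crawling-track
# statistics on annotated synthetic inputs.

suppressMessages(library(temsig))
dir.create("results", showWarnings = FALSE)

field <- c(400, 400)
for (attr_ in c(0, 0.8)) {
  wp <- read.csv(sprintf("results/wave_points_attraction_%02.0f.csv",
                         100 * attr_))
  wc <- wave_comparison(wp[wp$wave == 1, ], wp[wp$wave == 2, ], field,
                        seed = 101, target_radius_um = 7.5)
  write.csv(wc$distances,
            sprintf("results/distances_attraction_%02.0f.csv", 100 * attr_),
            row.names = FALSE)
  message(sprintf(
    "attraction %.1f: wave-2 median %.1f um, random median %.1f um (diff %.1f), KS p = %.3f",
    attr_, wc$summary$median[wc$summary$set == "wave2"],
    wc$summary$median[wc$summary$set == "random"],
    wc$median_difference, wc$ks_p))
}

# adhesion / diapedesis on annotated positions: the motivating regime is
# ~90% first-wave diapedesis with more second-wave adhesion on hotspots
set.seed(5)
pts <- rbind(
  data.frame(wave = 1, state = sample(c(rep("transmigrated", 90),
                                        rep("adherent", 10)))),
  data.frame(wave = 2, state = sample(c(rep("transmigrated", 105),
                                        rep("adherent", 45))))
)
m <- adhesion_metrics(pts)
print(m$per_wave, row.names = FALSE)
message(sprintf("wave2/wave1 adhesion ratio: %.2f", m$adhesion_ratio))

# crawling tracks: random walks with drift, 5 s frames
tracks <- do.call(rbind, lapply(1:25, function(id) {
  n <- sample(5:40, 1)
  data.frame(track_id = id, frame = seq_len(n) - 1,
             x = cumsum(rnorm(n, 0.5, 0.4)), y = cumsum(rnorm(n, 0, 0.4)))
}))
st <- track_statistics(tracks, frame_interval_s = 5)
write.csv(st, "results/track_stats.csv", row.names = FALSE)
message(sprintf(
  "crawling: median speed %.2f um/s, median length %.1f um, median duration %.0f s",
  median(st$speed_um_s), median(st$length_um), median(st$duration_s)))
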