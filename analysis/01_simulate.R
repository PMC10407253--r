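#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analyses:
# single-cell C/N traces for the control and neutrophil conditions, two-wave
# adhesion point sets with and without hotspot attraction, a filopodia spot
# field, and FRAP/FRET traces. Everything is seeded and annotated with
# ground truth so later steps can report recovery, not just output.

suppressMessages(library(temsig))
dir.create("results", showWarnings = FALSE)

seed <- 1L

# --- KTR traces: 200 cells per condition, 30 frames / 30 s, stimulus at 5
for (cond in c("control", "neutrophil")) {
  tr <- gen_traces(200, ktr_preset(cond), n_frames = 30, stimulus_frame = 5,
                   seed = seed + ifelse(cond == "control", 0L, 10000L))
  long <- data.frame(
    cell = rep(seq_len(nrow(tr$cn)), times = ncol(tr$cn)),
    frame = rep(seq_len(ncol(tr$cn)) - 1L, each = nrow(tr$cn)),
    cn_ratio = as.vector(tr$cn),
    condition = cond
  )
  write.csv(long, sprintf("results/traces_%s.csv", cond), row.names = FALSE)
  write.csv(cbind(tr$truth, condition = cond),
            sprintf("results/truth_%s.csv", cond), row.names = FALSE)
  message(sprintf("%s: %d cells, %d responders planted", cond,
                  nrow(tr$cn), sum(tr$truth$responder)))
}

# --- two-wave adhesion point sets
for (attr_ in c(0, 0.8)) {
  wp <- gen_wave_points(150, 150, field = c(400, 400),
                        hotspot_attraction = attr_, seed = seed)
  write.csv(wp, sprintf("results/wave_points_attraction_%02.0f.csv",
                        100 * attr_), row.names = FALSE)
}
message("wave point sets written (attraction 0 and 0.8)")

# --- filopodia field ground truth (the image itself is re-generated on
#     demand by 04_filopodia.R; only the text truth is kept)
f <- gen_filopodia_field(field_um = c(200, 200), density_per_um2 = 0.005,
                         seed = seed)
write.csv(f$spots, "results/filopodia_truth.csv", row.names = FALSE)
message(sprintf("filopodia field: %d spots planted (%d junctional)",
                nrow(f$spots), sum(f$spots$on_junction)))

# --- ratiometric traces
write.csv(gen_frap_trace(recovery_fraction = 0.7, noise_sd = 0.01, seed = seed),
          "results/frap_trace.csv", row.names = FALSE)
write.csv(gen_fret_traces(step_frame = 10, step_factor = 1.5,
                          noise_sd = 0.01, seed = seed),
          "results/fret_traces.csv", row.names = FALSE)
message("ratiometric traces written")
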