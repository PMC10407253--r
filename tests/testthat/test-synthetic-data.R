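test_that("gen_traces follows the closed-form response and exact responder counts", {
  pre <- ktr_preset("neutrophil", responder_rate = 1, noise_sd = 0,
                    baseline_cn = c(1, 1))
  tr <- gen_traces(1, pre, n_frames = 20, stimulus_frame = 5, seed = 1)
  t <- 0:19
  onset <- 5 + pre$rise_delay_frames
  expected <- 1 + ifelse(t >= onset, 0.4 * (1 - exp(-(t - onset) / 2)), 0)
  expect_equal(unname(tr$cn[1, ]), expected, tolerance = 1e-12)

  # responder counts are round(rate * n), never binomial
  expect_identical(sum(gen_traces(200, ktr_preset("control"), seed = 3)$truth$responder), 10L)
  expect_identical(sum(gen_traces(200, ktr_preset("neutrophil"), seed = 3)$truth$responder), 100L)
  expect_identical(sum(gen_traces(200, ktr_preset("control",
    responder_rate = 0.2), seed = 3)$truth$responder), 40L)

  # different seeds: different noise, same count
  a <- gen_traces(50, ktr_preset("neutrophil"), seed = 1)
  b <- gen_traces(50, ktr_preset("neutrophil"), seed = 2)
  expect_false(identical(a$cn, b$cn))
  expect_identical(sum(a$truth$responder), sum(b$truth$responder))
  # same seed: bit-identical
  expect_identical(a$cn, gen_traces(50, ktr_preset("neutrophil"), seed = 1)$cn)
})

test_that("non-responders stay at baseline and responders rise after the stimulus", {
  tr <- gen_traces(40, ktr_preset("neutrophil", noise_sd = 0), seed = 2)
  act <- tr$activity
  nonresp <- !tr$truth$responder
  expect_true(all(act[nonresp, ] == act[nonresp, 1]))
  resp <- act[tr$truth$responder, , drop = FALSE]
  post <- resp[, 8:ncol(resp), drop = FALSE]   # past the onset
  expect_true(all(apply(post, 1, function(x) all(diff(x) > 0))))
  expect_true(all(resp[, 1:6] == 0))
})

test_that("noise-free rendered movies reproduce the analytic C/N at every frame", {
  spec <- scene_spec(n_cells = 3, field_size_px = c(256, 256), n_frames = 6,
                     stimulus_frame = 2, seed = 5)
  pre <- ktr_preset("neutrophil", responder_rate = 1, noise_sd = 0)
  mv <- gen_ktr_movie(spec, pre)
  h <- dim(mv$ktr)[1]; w <- dim(mv$ktr)[2]
  all_nuc <- matrix(FALSE, h, w)
  for (i in 1:3) {
    ci <- mv$truth$cells[i, ]
    all_nuc <- all_nuc | truth_disk(h, w, ci$row, ci$col, ci$nucleus_d)
  }
  expect_true(all(mv$nuclear[, , 1][!all_nuc] == 0))  # only nuclei lit
  for (i in 1:3) {
    ci <- mv$truth$cells[i, ]
    nuc <- truth_disk(h, w, ci$row, ci$col, ci$nucleus_d)
    cell <- truth_disk(h, w, ci$row, ci$col, ci$cell_d)
    cyto <- cell & !nuc
    for (f in 1:6) {
      cn <- mean(mv$ktr[, , f][cyto]) / mean(mv$ktr[, , f][nuc])
      expect_equal(cn, unname(mv$truth$cn[i, f]), tolerance = 1e-6)
    }
    # conservation: total KTR signal of the cell is constant over time
    totals <- vapply(1:6, function(f) sum(mv$ktr[, , f][cell]), numeric(1))
    expect_equal(max(totals) - min(totals), 0, tolerance = 1e-9 * totals[1])
  }
})

test_that("movie generation is deterministic and errors on impossible density", {
  spec <- scene_spec(n_cells = 4, field_size_px = c(256, 256), n_frames = 3,
                     stimulus_frame = 1, seed = 9)
  pre <- ktr_preset("control")
  a <- gen_ktr_movie(spec, pre)
  b <- gen_ktr_movie(spec, pre)
  expect_identical(a$nuclear, b$nuclear)
  expect_identical(a$ktr, b$ktr)

  crowded <- scene_spec(n_cells = 60, field_size_px = c(256, 256),
                        n_frames = 2, stimulus_frame = 1)
  expect_error(gen_ktr_movie(crowded, pre), "density limit")
})

test_that("stimulus timing matches the acquisition layout", {
  spec <- scene_spec(n_frames = 30, frame_interval_s = 30, stimulus_frame = 5)
  expect_equal(spec$stimulus_frame * spec$frame_interval_s / 60, 2.5)
  expect_equal(spec$n_frames * spec$frame_interval_s / 60, 15)
  expect_error(scene_spec(stimulus_frame = 30, n_frames = 30))
  expect_error(scene_spec(pixel_size_um = 0))
  expect_error(scene_spec(nucleus_diameter_px = c(60, 70), cell_diameter_px = 60))
})

test_that("wave-point generator honours attraction, radius and empty waves", {
  # attraction 1: every second-wave point within the radius of a wave-1 point
  wp <- gen_wave_points(80, 60, field = c(300, 300), hotspot_attraction = 1,
                        attract_radius_um = 5, seed = 4)
  w1 <- wp[wp$wave == 1, ]; w2 <- wp[wp$wave == 2, ]
  d <- signed_nn_distance(w2, w1)
  expect_true(all(d <= 5 + 1e-9))
  expect_true(all(w2$attracted))

  # attraction 0: median NN distance matches a Monte-Carlo uniform-null oracle
  wp0 <- gen_wave_points(80, 200, field = c(300, 300), hotspot_attraction = 0,
                         seed = 11)
  w1 <- wp0[wp0$wave == 1, ]
  obs <- median(signed_nn_distance(wp0[wp0$wave == 2, ], w1))
  set.seed(99)
  mc <- replicate(200, {
    u <- data.frame(x_um = runif(200, 0, 300), y_um = runif(200, 0, 300))
    median(signed_nn_distance(u, w1))
  })
  expect_lt(abs(obs - mean(mc)), 3 * sd(mc) + 1e-9)

  # empty second wave: no error, zero rows
  e <- gen_wave_points(10, 0, seed = 1)
  expect_identical(sum(e$wave == 2), 0L)
})

test_that("filopodia fields plant round(density * area) separated spots with junction truth", {
  f <- gen_filopodia_field(field_um = c(200, 200), density_per_um2 = 0.005,
                           seed = 2)
  expect_identical(nrow(f$spots), 200L)
  dmat <- as.matrix(dist(f$spots[, c("x_um", "y_um")]))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 2 * 0.6)
  # ground-truth junction flags agree with the mask at the spot centres
  expect_identical(f$spots$on_junction,
                   f$junction_mask[cbind(f$spots$row, f$spots$col)])

  f0 <- gen_filopodia_field(density_per_um2 = 0, seed = 1)
  expect_identical(nrow(f0$spots), 0L)

  expect_error(gen_filopodia_field(field_um = c(20, 20), density_per_um2 = 0.5),
               "too high")
})

test_that("ratiometric generators obey their closed forms", {
  # FRAP: noise-free recovery fraction 0.7 normalizes to a 70% plateau
  tr <- gen_frap_trace(recovery_fraction = 0.7, noise_sd = 0, tau_s = 10)
  nm <- frap_normalize(tr)
  expect_equal(nm$percent[nm$time_s == 0], 100)
  expect_equal(nm$percent[nm$time_s == 15], 0)
  expect_equal(tail(nm$percent, 1), 70, tolerance = 0.1)

  # FRET: ratio steps by the stated factor at the stated frame
  ft <- gen_fret_traces(step_frame = 10, step_factor = 1.5, noise_sd = 0)
  r <- ft$acceptor / ft$donor
  expect_equal(unique(r[ft$frame < 10]), 1)
  expect_equal(unique(r[ft$frame >= 10]), 1.5)

  # crosstalk: planted 2% bleed is recovered by the forward model
  bl <- diag(3); bl[1, 2] <- 0.02; bl[2, 3] <- 0.05
  st <- gen_crosstalk_stacks(bl, noise_sd = 0)
  M <- crosstalk_matrix(st)
  expect_equal(M[1, 2], 0.02, tolerance = 0.002)
  expect_equal(M[2, 3], 0.05, tolerance = 0.002)
  expect_identical(unname(diag(M)), rep(1, 3))

  # umbrella dispatcher reaches the same generators
  expect_identical(gen_ratiometric_traces("frap", list(recovery_fraction = 0.5)),
                   gen_frap_trace(recovery_fraction = 0.5))
})
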