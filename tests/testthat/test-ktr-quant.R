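test_that("background subtraction flattens constants and matches a naive opening oracle", {
  expect_equal(subtract_background(matrix(0.7, 30, 30), 5),
               matrix(0, 30, 30))
  expect_equal(subtract_background(matrix(0, 30, 30), 5),
               matrix(0, 30, 30))
  expect_error(subtract_background(matrix(0, 5, 5), 0), "radius")

  # constant + one bright disk smaller than the ball: disk preserved
  img <- matrix(0.2, 48, 48)
  disk <- truth_disk(48, 48, 24, 24, 8)
  img[disk] <- 0.2 + 0.5
  out <- subtract_background(img, radius_px = 10)
  expect_equal(mean(out[disk]), 0.5, tolerance = 0.05 * 0.5)
  # oracle: naive erode-then-dilate opening
  ref <- img - naive_opening(img, 10)
  expect_equal(out[disk], ref[disk], tolerance = 1e-9)
})

test_that("nucleus segmentation recovers planted disks and applies the size filters", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)

  img <- matrix(0, 400, 400)
  centers <- expand.grid(r = c(60, 160, 260, 360) - 20, c = c(80, 200, 320))
  centers <- centers[1:10, ]
  for (k in 1:10) img[truth_disk(400, 400, centers$r[k], centers$c[k], 40)] <- 0.5
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 10)
  cent <- t(vapply(1:10, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  # every planted centre has a segmented centroid within 1 px
  for (k in 1:10) {
    d <- sqrt((cent[, 1] - centers$r[k])^2 + (cent[, 2] - centers$c[k])^2)
    expect_lt(min(d), 1)
  }

  # a 20 px disk is below d_min = 30 and must vanish
  small <- matrix(0, 128, 128)
  small[truth_disk(128, 128, 64, 64, 20)] <- 0.5
  expect_equal(max(segment_nuclei(small)), 0)

  # border-touching nuclei are dropped
  edge <- matrix(0, 128, 128)
  edge[truth_disk(128, 128, 5, 64, 40)] <- 0.5
  expect_equal(max(segment_nuclei(edge)), 0)
})

test_that("cytoplasm is a ring around the nucleus, split by the nearest-nucleus rule", {
  # single nucleus on uniformly bright KTR: the cytoplasm is a 10 px annulus
  img <- matrix(0, 128, 128)
  nucmask <- truth_disk(128, 128, 64, 64, 36)
  img[nucmask] <- 0.5
  nl <- segment_nuclei(img)
  seg <- segment_cytoplasm(nl, matrix(0.5, 128, 128))
  cyto <- seg$cytoplasm > 0
  d_out <- sqrt((row(img) - 64)^2 + (col(img) - 64)^2) - 18
  expect_true(all(d_out[cyto] > -1.5 & d_out[cyto] <= 10.5))
  expect_true(sum(cyto) > 0.9 * sum(d_out > 0.5 & d_out <= 9.5))
  # nucleus and cytoplasm are disjoint
  expect_true(all((nl > 0) + (seg$cytoplasm > 0) <= 1))

  # two nuclei 45 px apart: collision pixels split by nearest nucleus
  img2 <- matrix(0, 120, 160)
  img2[truth_disk(120, 160, 60, 58, 36)] <- 0.5
  img2[truth_disk(120, 160, 60, 103, 36)] <- 0.5
  nl2 <- segment_nuclei(img2)
  expect_equal(max(nl2), 2)
  seg2 <- segment_cytoplasm(nl2, matrix(0.5, 120, 160))
  ref <- naive_nearest_nucleus(nl2, seg2$cells > 0)
  agree <- mean(seg2$cells[seg2$cells > 0] == ref[seg2$cells > 0])
  expect_gte(agree, 0.99)
  # cytoplasm sets of different cells are disjoint by construction
  expect_true(all(seg2$cytoplasm[nl2 > 0] == 0))

  # KTR below threshold everywhere: empty cytoplasm, cells flagged
  seg3 <- segment_cytoplasm(nl2, matrix(0.01, 120, 160))
  expect_equal(sort(seg3$unmeasurable), c(1, 2))
  expect_equal(max(seg3$cytoplasm), 0)

  expect_error(segment_cytoplasm(nl2, matrix(0.5, 10, 10)), "shape")
})

test_that("C/N measurement follows its definition and flags tiny compartments", {
  img <- matrix(0, 128, 128)
  img[truth_disk(128, 128, 64, 64, 36)] <- 0.5
  nl <- segment_nuclei(img)
  seg <- segment_cytoplasm(nl, matrix(0.5, 128, 128))

  # uniform image: C/N = 1
  m <- measure_cn(nl, seg$cytoplasm, matrix(0.7, 128, 128))
  expect_equal(m$cn_ratio, 1)

  # nucleus mean 2, cytoplasm mean 4: C/N = 2
  ktr <- matrix(0, 128, 128)
  ktr[nl > 0] <- 2; ktr[seg$cytoplasm > 0] <- 4
  m2 <- measure_cn(nl, seg$cytoplasm, ktr)
  expect_equal(m2$cn_ratio, 2)
  expect_equal(m2$nuc_mean, 2)
  expect_equal(m2$cyto_mean, 4)

  # C/N is invariant to positive rescaling of the KTR image
  m3 <- measure_cn(nl, seg$cytoplasm, ktr * 37.5)
  expect_equal(m3$cn_ratio, m2$cn_ratio)

  # a cytoplasm below min_pixels yields NA, not zero
  tiny <- seg$cytoplasm
  keep <- which(tiny > 0)
  tiny[keep[-(1:5)]] <- 0L
  m4 <- measure_cn(nl, tiny, ktr)
  expect_true(is.na(m4$cn_ratio))
})

test_that("overlap tracking links static and slowly drifting cells and splits jumps", {
  mk <- function(centers) {
    lab <- matrix(0L, 96, 96)
    for (k in seq_len(nrow(centers))) {
      lab[truth_disk(96, 96, centers[k, 1], centers[k, 2], 20)] <- k
    }
    lab
  }
  # static scene: one track per cell over all frames
  frames <- replicate(5, mk(rbind(c(30, 30), c(60, 66))), simplify = FALSE)
  tr <- track_overlap(frames)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(nrow(tr), 10)

  # 2 px/frame drift: single unbroken track
  drift <- lapply(0:4, function(f) mk(rbind(c(30 + 2 * f, 30))))
  tr2 <- track_overlap(drift)
  expect_equal(length(unique(tr2$track_id)), 1)

  # 10 px jumps exceed the 3 px gate: a new track every frame
  jump <- lapply(0:4, function(f) mk(rbind(c(20 + 10 * f, 48))))
  tr3 <- track_overlap(jump)
  expect_equal(length(unique(tr3$track_id)), 5)

  # determinism
  expect_identical(track_overlap(drift), track_overlap(drift))

  # pure-distance fallback links non-overlapping small objects
  far <- lapply(0:2, function(f) {
    lab <- matrix(0L, 40, 40); lab[20 + 2 * f, 20] <- 1L; lab
  })
  expect_equal(length(unique(track_overlap(far, require_overlap = FALSE)$track_id)), 1)
  expect_equal(length(unique(track_overlap(far, require_overlap = TRUE)$track_id)), 3)
})

test_that("the full pipeline recovers noise-free ground truth and handles 1-frame movies", {
  spec <- scene_spec(n_cells = 5, field_size_px = c(300, 300), n_frames = 6,
                     stimulus_frame = 2, seed = 21)
  pre <- ktr_preset("neutrophil", responder_rate = 1, noise_sd = 0)
  mv <- gen_ktr_movie(spec, pre)
  tab <- run_ktr_pipeline(mv$nuclear, mv$ktr)
  expect_equal(length(unique(tab$track_id)), 5)

  first <- tab[tab$frame == 0, ]
  for (i in 1:5) {
    d <- sqrt((first$y_px + 1 - mv$truth$cells$row[i])^2 +
              (first$x_px + 1 - mv$truth$cells$col[i])^2)
    j <- which.min(d)
    expect_lt(min(d), 3)
    tt <- tab[tab$track_id == first$track_id[j] & tab$present, ]
    expect_equal(nrow(tt), 6)
    rel <- abs(tt$cn_ratio - mv$truth$cn[i, tt$frame + 1]) /
      mv$truth$cn[i, tt$frame + 1]
    expect_lt(max(rel), 1e-3)
  }

  # single-frame movie: valid table, all tracks length 1
  tab1 <- run_ktr_pipeline(mv$nuclear[, , 1, drop = FALSE],
                           mv$ktr[, , 1, drop = FALSE])
  expect_equal(as.integer(table(tab1$track_id)), rep(1L, 5))
  expect_true(all(tab1$frame == 0))

  # empty stack and all-empty segmentation produce explicit errors
  expect_error(run_ktr_pipeline(array(0, c(64, 64, 0)), array(0, c(64, 64, 0))),
               "empty")
  expect_error(run_ktr_pipeline(array(0, c(64, 64, 2)), array(0, c(64, 64, 2))),
               "no nuclei")
})
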