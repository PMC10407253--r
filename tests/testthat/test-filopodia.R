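test_that("LoG spot detection finds planted spots with sub-pixel accuracy", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64), 0.15)), 0)
  expect_equal(nrow(detect_spots(matrix(0.4, 64, 64), 0.15)), 0)
  expect_error(detect_spots(matrix(0, 64, 64), pixel_size_um = 0.4), "coarse")

  f <- gen_filopodia_field(density_per_um2 = 0.005, junction_lines = FALSE,
                           seed = 8)
  sp <- filter_spots(detect_spots(f$image, f$pixel_size_um), 0.25)
  planted <- f$spots
  hits <- vapply(seq_len(nrow(planted)), function(i) {
    min(sqrt((sp$x_um - planted$x_um[i])^2 + (sp$y_um - planted$y_um[i])^2))
  }, numeric(1))
  expect_gte(mean(hits <= 0.3), 0.95)          # >= 95% matched within 0.3 um
  expect_lte(nrow(sp) - sum(hits <= 0.3), 0.05 * nrow(planted))  # <= 5% spurious
})

test_that("detector quality preserves amplitude ordering and density survives rescaling", {
  img <- matrix(0.05, 128, 128)
  add_spot <- function(im, r0, c0, amp, sigma = 1.7) {
    ri <- (r0 - 8):(r0 + 8); ci <- (c0 - 8):(c0 + 8)
    im[ri, ci] <- im[ri, ci] +
      amp * exp(-(outer((ri - r0)^2, (ci - c0)^2, `+`)) / (2 * sigma^2))
    im
  }
  img <- add_spot(img, 40, 40, 0.3)
  img <- add_spot(img, 90, 90, 0.6)
  sp <- detect_spots(img, 0.15)
  sp <- sp[order(-sp$quality), ]
  expect_equal(c(sp$row[1], sp$col[1]), c(90, 90))  # 2A spot outranks A

  # intensity rescaling leaves relative qualities, hence the kept set, alone
  sp2 <- detect_spots(img * 12, 0.15)
  expect_equal(sort(sp2$quality_rel), sort(sp$quality_rel), tolerance = 1e-9)
  expect_equal(nrow(filter_spots(sp2, 0.25)), nrow(filter_spots(sp, 0.25)))
})

test_that("junction masks have the stated geometry and filtering is exact and idempotent", {
  # synthetic ridge 1 um wide, dilation 0.5 um: mask width 2 um +/- 1 px
  px <- 0.1
  img <- matrix(0, 100, 200)
  rr <- (row(img) - 0.5) * px
  img[abs(rr - 5) <= 0.5] <- 0.8
  mask <- junction_mask_from_channel(img, 0.4, dilation_um = 0.5,
                                     pixel_size_um = px)
  width_um <- max(colSums(mask)) * px
  expect_lte(abs(width_um - 2), px + 1e-9)

  expect_equal(sum(junction_mask_from_channel(matrix(0, 50, 50), 0.1,
                                              pixel_size_um = px)), 0)
  expect_warning(junction_mask_from_channel(matrix(1, 20, 20), 0.5,
                                            pixel_size_um = px), "whole frame")

  # planted junctional/free mix: exactly the free spots survive the mask
  f <- gen_filopodia_field(density_per_um2 = 0.01, junction_lines = TRUE,
                           n_junctions = 10, seed = 5)
  gt <- f$spots
  gt$quality <- 1; gt$quality_rel <- 1; gt$scale_um <- 0.6
  kept <- filter_spots(gt, 0, junction_mask = f$junction_mask)
  expect_identical(nrow(kept), sum(!gt$on_junction))
  expect_equal(attr(kept, "removed_junction"), sum(gt$on_junction))

  # threshold 0 and no mask: identity; filtering twice changes nothing
  all_kept <- filter_spots(gt, 0)
  expect_equal(nrow(all_kept), nrow(gt))
  twice <- filter_spots(filter_spots(gt, 0.5, f$junction_mask), 0.5,
                        f$junction_mask)
  expect_equal(nrow(twice), nrow(filter_spots(gt, 0.5, f$junction_mask)))
})

test_that("density arithmetic and the GFP mosaic split behave as stated", {
  sp <- data.frame(x_um = runif(50), y_um = runif(50),
                   row = sample(10, 50, TRUE), col = sample(10, 50, TRUE),
                   quality = 1, quality_rel = 1)
  expect_equal(spot_density(sp, 100 * 100)$density, 0.005)
  expect_equal(spot_density(sp[0, ], 100)$density, 0)
  expect_error(spot_density(sp, 0), "area")

  # mosaic: doubled planted density on the GFP+ half recovers a 2.0 ratio
  set.seed(41)
  px <- 0.5; n_side <- 200  # 100 x 100 um field
  gfp <- matrix(0, n_side, n_side)
  gfp[, 1:(n_side / 2)] <- 1  # left half transduced
  n_pos <- 100; n_neg <- 50
  mk <- function(n, cmin, cmax) data.frame(
    row = runif(n, 1, n_side), col = runif(n, cmin, cmax))
  pts <- rbind(mk(n_pos, 1, n_side / 2), mk(n_neg, n_side / 2 + 1, n_side))
  pts$row <- round(pts$row); pts$col <- round(pts$col)
  pts$x_um <- pts$col * px; pts$y_um <- pts$row * px
  pts$quality <- 1; pts$quality_rel <- 1
  d <- spot_density(pts, 100 * 100, gfp_image = gfp, gfp_threshold = 0.5,
                    pixel_size_um = px)
  ratio <- d$by_gfp$density[d$by_gfp$partition == "transduced"] /
    d$by_gfp$density[d$by_gfp$partition == "untransduced"]
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("morphometry recovers a Voronoi monolayer and applies the stated filters", {
  # build a synthetic monolayer: Voronoi cells around seed nuclei,
  # junction channel = ridges on the Voronoi boundaries
  set.seed(17)
  h <- 300; w <- 300; px <- 0.5
  ctr <- cbind(r = c(70, 80, 200, 220, 150), c = c(70, 220, 80, 220, 150))
  dists <- array(Inf, c(h, w, nrow(ctr)))
  for (k in seq_len(nrow(ctr))) {
    dists[, , k] <- (row(matrix(0, h, w)) - ctr[k, "r"])^2 +
      (col(matrix(0, h, w)) - ctr[k, "c"])^2
  }
  vor <- apply(dists, c(1, 2), which.min)
  edge <- matrix(FALSE, h, w)
  edge[-1, ] <- edge[-1, ] | (diff(vor) != 0)
  edge[, -1] <- edge[, -1] | (t(diff(t(vor))) != 0)
  jun <- matrix(0, h, w)
  jun[edge] <- 0.9
  jun <- EBImage::imageData(EBImage::gblur(EBImage::Image(jun), 1.5))
  nuc <- matrix(0, h, w)
  for (k in seq_len(nrow(ctr))) {
    nuc[truth_disk(h, w, ctr[k, "r"], ctr[k, "c"], 24)] <- 0.8
  }
  icam <- matrix(0, h, w)
  for (k in seq_len(nrow(ctr))) icam[vor == k] <- 0.1 * k

  morph <- cell_morphometry(nuc, jun, icam, pixel_size_um = px)
  # only the centre cell is fully in frame
  expect_equal(nrow(morph), 1)
  truth_area <- sum(vor == 5) * px^2
  expect_lt(abs(morph$area_um2 - truth_area) / truth_area, 0.05)
  expect_equal(morph$icam_mean, 0.5, tolerance = 0.05)

  # a lone circular cell bounded by a ring junction is near-circular
  h2 <- 160
  nuc2 <- matrix(0, h2, h2); nuc2[truth_disk(h2, h2, 80, 80, 26)] <- 0.8
  rad <- sqrt((row(nuc2) - 80)^2 + (col(nuc2) - 80)^2)
  jun2 <- matrix(0, h2, h2); jun2[abs(rad - 55) < 2] <- 0.9
  m2 <- cell_morphometry(nuc2, jun2, nuc2 * 0, pixel_size_um = px)
  expect_equal(nrow(m2), 1)
  expect_gte(m2$circularity, 0.95)

  # nuclei under 173 px are filtered out (a 10 px disk is ~78 px)
  nuc3 <- matrix(0, h2, h2); nuc3[truth_disk(h2, h2, 80, 80, 10)] <- 0.8
  m3 <- cell_morphometry(nuc3, jun2, nuc2 * 0, pixel_size_um = px,
                         params = list(nucleus_scale_um = 2))
  expect_equal(nrow(m3), 0)
})
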