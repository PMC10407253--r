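#' Generate two sequential waves of adherent-cell positions
#'
#' First-wave neutrophils cluster around a few hotspot centres; a stated
#' fraction of second-wave points lands within `attract_radius_um` of a
#' randomly chosen first-wave point (hotspot reuse) and the rest are
#' uniform over the field. `hotspot_attraction = 0` gives a fully uniform
#' second wave; `1` puts every second-wave point within the radius of a
#' first-wave point.
#'
#' @param n_first,n_second numbers of points per wave.
#' @param field length-2 numeric, field width and height in micrometres.
#' @param hotspot_attraction fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param n_hotspots number of first-wave hotspot centres (default 5).
#' @param hotspot_sd_um scatter of first-wave points around their hotspot
#'   (default 15).
#' @param attract_radius_um radius of the attraction disk (default 5).
#' @return data.frame with `x_um`, `y_um`, `wave` (1 or 2), `attracted`
#'   (logical ground truth; NA for wave 1).
#' @export
gen_wave_points <- function(n_first, n_second, field = c(400, 400),
                            hotspot_attraction = 0.5, seed = 1L,
                            n_hotspots = 5L, hotspot_sd_um = 15,
                            attract_radius_um = 5) {
  stopifnot(hotspot_attraction >= 0, hotspot_attraction <= 1,
            n_first >= 1, n_second >= 0, all(field > 0))
  set.seed(seed)
  hx <- runif(n_hotspots, 0.15 * field[1], 0.85 * field[1])
  hy <- runif(n_hotspots, 0.15 * field[2], 0.85 * field[2])
  hs <- sample.int(n_hotspots, n_first, replace = TRUE)
  w1 <- data.frame(
    x_um = clamp(rnorm(n_first, hx[hs], hotspot_sd_um), 0, field[1]),
    y_um = clamp(rnorm(n_first, hy[hs], hotspot_sd_um), 0, field[2]),
    wave = 1L, attracted = NA
  )
  if (n_second == 0) {
    return(rbind(w1, w1[0, ]))
  }
  n_attr <- round(hotspot_attraction * n_second)
  attracted <- c(rep(TRUE, n_attr), rep(FALSE, n_second - n_attr))
  xs <- numeric(n_second); ys <- numeric(n_second)
  if (n_attr > 0) {
    anchor <- sample.int(n_first, n_attr, replace = TRUE)
    # uniform over the disk of the attraction radius
    r <- attract_radius_um * sqrt(runif(n_attr))
    th <- runif(n_attr, 0, 2 * pi)
    xs[attracted] <- clamp(w1$x_um[anchor] + r * cos(th), 0, field[1])
    ys[attracted] <- clamp(w1$y_um[anchor] + r * sin(th), 0, field[2])
  }
  if (n_attr < n_second) {
    xs[!attracted] <- runif(n_second - n_attr, 0, field[1])
    ys[!attracted] <- runif(n_second - n_attr, 0, field[2])
  }
  w2 <- data.frame(x_um = xs, y_um = ys, wave = 2L, attracted = attracted)
  rbind(w1, w2)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic filopodia spot field with ground truth
#'
#' Renders diffraction-limited spots (isotropic Gaussians of stated FWHM)
#' at a known density on a membrane-textured background, optionally with
#' bright junction ridges. Planted spots keep a minimal separation of two
#' diameters so that detection performance reflects the detector, not spot
#' fusion. Spots may fall on junction lines; the ground truth flags them.
#'
#' @param field_um length-2 field size in micrometres (default 200 x 200).
#' @param density_per_um2 planted spot density; count is
#'   `round(density * area)`.
#' @param pixel_size_um rendering pixel size (default 0.15).
#' @param spot_diameter_um spot FWHM (default 0.6).
#' @param spot_amplitude peak spot intensity above background (default 0.5).
#' @param junction_lines draw bright junction ridges (default TRUE).
#' @param n_junctions number of ridge lines (default 6).
#' @param junction_width_um ridge full width (default 1).
#' @param junction_level ridge intensity (default 0.35).
#' @param texture_sd amplitude of the smooth membrane texture
#'   (default 0.03).
#' @param seed integer seed.
#' @return list with `image` (H x W matrix), `spots` (ground-truth table:
#'   `x_um`, `y_um`, `row`, `col`, `on_junction`), `junction_mask` (logical
#'   matrix, all-FALSE if no ridges), `pixel_size_um`, `area_um2`.
#' @export
gen_filopodia_field <- function(field_um = c(200, 200), density_per_um2,
                                pixel_size_um = 0.15, spot_diameter_um = 0.6,
                                spot_amplitude = 0.5, junction_lines = TRUE,
                                n_junctions = 6L, junction_width_um = 1,
                                junction_level = 0.35, texture_sd = 0.03,
                                seed = 1L) {
  stopifnot(density_per_um2 >= 0, all(field_um > 0))
  set.seed(seed)
  h <- round(field_um[2] / pixel_size_um)
  w <- round(field_um[1] / pixel_size_um)
  area <- prod(field_um)
  n <- round(density_per_um2 * area)
  min_sep <- 2 * spot_diameter_um
  margin <- 2 * spot_diameter_um

  # feasibility at the stated separation (loose packing bound on the
  # placeable area inside the margins)
  usable <- prod(pmax(field_um - 2 * margin, 0))
  if (n > 0 && n * pi * (min_sep / 2)^2 > 0.55 * usable) {
    stop(sprintf("density %g/um^2 too high to keep spots %g um apart",
                 density_per_um2, min_sep))
  }
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L; max_tries <- 400L * max(n, 1L)
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf("density too high: could not place %d spots with %g um separation",
                   n, min_sep))
    }
    cx <- runif(1, margin, field_um[1] - margin)
    cy <- runif(1, margin, field_um[2] - margin)
    if (length(xs) > 0 && min((xs - cx)^2 + (ys - cy)^2) < min_sep^2) next
    xs <- c(xs, cx); ys <- c(ys, cy)
  }

  # membrane texture: heavily smoothed white noise, zero-mean
  img <- matrix(0.1, h, w)
  if (texture_sd > 0) {
    tex <- matrix(rnorm(h * w), h, w)
    tex <- EBImage::imageData(EBImage::gblur(EBImage::Image(tex),
                                             sigma = 1 / pixel_size_um))
    tex <- tex / stats::sd(tex) * texture_sd
    img <- img + tex - mean(tex)
  }

  jmask <- matrix(FALSE, h, w)
  if (junction_lines && n_junctions > 0) {
    half_w <- junction_width_um / 2
    rr <- (row(img) - 0.5) * pixel_size_um
    cc <- (col(img) - 0.5) * pixel_size_um
    for (k in seq_len(n_junctions)) {
      th <- runif(1, 0, pi)
      d0 <- runif(1, 0, sqrt(sum(field_um^2)))
      dist_line <- abs(cc * cos(th) + rr * sin(th) - d0)
      jmask <- jmask | (dist_line <= half_w)
    }
    img <- img + junction_level * jmask
  }

  sigma_um <- spot_diameter_um / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  sigma_px <- sigma_um / pixel_size_um
  half <- ceiling(4 * sigma_px)
  on_j <- logical(n)
  rows <- ys / pixel_size_um + 0.5
  cols <- xs / pixel_size_um + 0.5
  for (i in seq_len(n)) {
    r0 <- rows[i]; c0 <- cols[i]
    ri <- max(1, floor(r0 - half)):min(h, ceiling(r0 + half))
    ci <- max(1, floor(c0 - half)):min(w, ceiling(c0 + half))
    patch <- spot_amplitude *
      exp(-(outer((ri - r0)^2, (ci - c0)^2, `+`)) / (2 * sigma_px^2))
    img[ri, ci] <- img[ri, ci] + patch
    on_j[i] <- jmask[round(r0), round(c0)]
  }
  list(image = img,
       spots = data.frame(x_um = xs, y_um = ys,
                          row = round(rows), col = round(cols),
                          on_junction = on_j),
       junction_mask = jmask,
       pixel_size_um = pixel_size_um,
       area_um2 = area)
}
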