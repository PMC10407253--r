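#' Detect diffraction-limited spots by Laplacian-of-Gaussian filtering
#'
#' Filters the image with a scale-normalized LoG kernel tuned to the
#' expected spot diameter (sigma = diameter / (2*sqrt(2)) in pixels, the
#' scale at which the LoG response of a Gaussian blob peaks) and reports
#' local maxima of the response with sub-pixel centres. The detector
#' response at the maximum is the spot `quality`; `quality_rel` is quality
#' divided by the strongest response in the image, which makes downstream
#' thresholds invariant to intensity rescaling.
#'
#' @param image 2D numeric matrix.
#' @param pixel_size_um pixel size, micrometres; must satisfy
#'   `pixel_size_um <= diameter_um / 2` (Nyquist for detection).
#' @param diameter_um expected spot diameter (default 0.6).
#' @param floor_rel discard maxima with response below this fraction of the
#'   maximal response (default 0.02; keeps the candidate list finite on
#'   textured backgrounds).
#' @return data.frame of class spot table: `x_um`, `y_um`, `row`, `col`
#'   (1-based pixel indices of the maximum), `scale_um`, `quality`,
#'   `quality_rel`.
#' @export
detect_spots <- function(image, pixel_size_um, diameter_um = 0.6,
                         floor_rel = 0.02) {
  if (pixel_size_um > diameter_um / 2) {
    stop(sprintf("pixel size %g um too coarse for %g um spots (need <= diameter/2)",
                 pixel_size_um, diameter_um))
  }
  img <- as_matrix2d(image)
  sigma <- diameter_um / (2 * sqrt(2)) / pixel_size_um
  resp <- log_response(img, sigma)
  mx <- local_maxima(resp)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), row = numeric(0),
                      col = numeric(0), scale_um = numeric(0),
                      quality = numeric(0), quality_rel = numeric(0))
  if (nrow(mx) == 0) return(empty)
  top <- max(mx$value)
  if (top <= 0) return(empty)
  mx <- mx[mx$value >= floor_rel * top, , drop = FALSE]
  # sub-pixel refinement: 1D quadratic fit along each axis
  off <- t(vapply(seq_len(nrow(mx)), function(k) {
    r <- mx$row[k]; c <- mx$col[k]
    c(quad_offset(resp[r - 1, c], resp[r, c], resp[r + 1, c]),
      quad_offset(resp[r, c - 1], resp[r, c], resp[r, c + 1]))
  }, numeric(2)))
  data.frame(
    x_um = (mx$col + off[, 2] - 1) * pixel_size_um,
    y_um = (mx$row + off[, 1] - 1) * pixel_size_um,
    row = mx$row, col = mx$col,
    scale_um = diameter_um,
    quality = mx$value,
    quality_rel = mx$value / top
  )
}

# scale-normalized negative LoG filter: positive response for bright blobs
log_response <- function(img, sigma) {
  half <- max(3L, ceiling(4 * sigma))
  ax <- seq(-half, half)
  r2 <- outer(ax^2, ax^2, `+`)
  g <- exp(-r2 / (2 * sigma^2))
  k <- -(r2 - 2 * sigma^2) / sigma^2 * g   # includes the sigma^2 normalization
  k <- k - mean(k)                          # zero DC: flat images respond 0
  EBImage::imageData(EBImage::filter2(EBImage::Image(img), k))
}

local_maxima <- function(resp) {
  h <- nrow(resp); w <- ncol(resp)
  if (h < 3 || w < 3) return(data.frame(row = integer(0), col = integer(0),
                                        value = numeric(0)))
  core <- resp[2:(h - 1), 2:(w - 1)]
  is_max <- core > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (core > resp[2:(h - 1) + dr, 2:(w - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
             value = core[is_max])
}

quad_offset <- function(a, b, c) {
  den <- 2 * (2 * b - a - c)
  if (den <= 0) return(0)
  max(-0.5, min(0.5, (a - c) / den))
}

#' Build a junction mask from a junction-marker channel
#'
#' Thresholds the junction channel (e.g. VE-cadherin) and dilates the mask
#' by a physical radius, producing the exclusion zone for junctional
#' signal.
#'
#' @param junction_image 2D matrix.
#' @param threshold intensity threshold.
#' @param dilation_um dilation radius in micrometres (default 0.5).
#' @param pixel_size_um pixel size.
#' @return logical matrix with attribute `fraction` (masked area fraction).
#'   A fully masked frame triggers a warning.
#' @export
junction_mask_from_channel <- function(junction_image, threshold,
                                       dilation_um = 0.5, pixel_size_um) {
  img <- as_matrix2d(junction_image)
  mask <- img > threshold
  r <- round(dilation_um / pixel_size_um)
  if (any(mask) && r >= 1) {
    mask <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(mask * 1), EBImage::makeBrush(2L * r + 1L, "disc"))) > 0
  }
  frac <- mean(mask)
  if (frac == 1) warning("junction mask covers the whole frame")
  structure(mask, fraction = frac)
}

#' Filter spots by detector quality and junctional location
#'
#' Drops spots with `quality_rel` below the threshold and spots whose
#' centre falls inside the junction mask (junctional signal is not counted
#' as filopodia). Removal counts are recorded in attributes
#' `removed_quality` and `removed_junction`. Applying the same filter twice
#' changes nothing.
#'
#' @param spots spot table from [detect_spots()].
#' @param quality_threshold threshold on `quality_rel` in `[0, 1]`
#'   (default 0.25).
#' @param junction_mask optional logical matrix from
#'   [junction_mask_from_channel()].
#' @return filtered spot table with an added `on_junction` column (all
#'   FALSE after filtering).
#' @export
filter_spots <- function(spots, quality_threshold = 0.25,
                         junction_mask = NULL) {
  ok_q <- spots$quality_rel >= quality_threshold
  on_j <- rep(FALSE, nrow(spots))
  if (!is.null(junction_mask) && nrow(spots) > 0) {
    on_j <- junction_mask[cbind(spots$row, spots$col)]
  }
  out <- spots[ok_q & !on_j, , drop = FALSE]
  out$on_junction <- FALSE
  rownames(out) <- NULL
  structure(out,
            removed_quality = sum(!ok_q),
            removed_junction = sum(on_j & ok_q))
}

#' Filopodia density per square micrometre
#'
#' Divides the number of kept spots by the imaged area. With a GFP channel
#' (mosaic overexpression experiments) spots and area are partitioned into
#' transduced (GFP at the spot centre at or above threshold) and
#' untransduced, and a density is reported for each partition over its own
#' area share.
#'
#' @param spots filtered spot table.
#' @param area_um2 imaged area, square micrometres (> 0).
#' @param gfp_image optional GFP channel (2D matrix).
#' @param gfp_threshold GFP intensity splitting transduced from
#'   untransduced.
#' @param pixel_size_um pixel size, required with `gfp_image`.
#' @return list with `density` (spots per um^2), `n_spots`, `area_um2` and,
#'   when a GFP split is requested, `by_gfp`: a data.frame with one row per
#'   partition (`transduced`, `untransduced`) giving `n_spots`, `area_um2`,
#'   `density`.
#' @export
spot_density <- function(spots, area_um2, gfp_image = NULL,
                         gfp_threshold = NULL, pixel_size_um = NULL) {
  if (area_um2 <= 0) stop("area_um2 must be > 0")
  out <- list(density = nrow(spots) / area_um2,
              n_spots = nrow(spots), area_um2 = area_um2)
  if (!is.null(gfp_image)) {
    stopifnot(!is.null(gfp_threshold), !is.null(pixel_size_um))
    gfp <- as_matrix2d(gfp_image)
    pos <- gfp >= gfp_threshold
    at_spot <- if (nrow(spots) > 0) gfp[cbind(spots$row, spots$col)] else numeric(0)
    trans <- at_spot >= gfp_threshold
    area_pos <- mean(pos) * area_um2
    area_neg <- area_um2 - area_pos
    out$by_gfp <- data.frame(
      partition = c("transduced", "untransduced"),
      n_spots = c(sum(trans), sum(!trans)),
      area_um2 = c(area_pos, area_neg),
      density = c(if (area_pos > 0) sum(trans) / area_pos else NA_real_,
                  if (area_neg > 0) sum(!trans) / area_neg else NA_real_)
    )
  }
  out
}

#' Monolayer morphometry from nuclear, junction and ICAM-1 channels
#'
#' Nuclei are detected at a stated physical scale (Gaussian smoothing +
#' threshold + distance-transform watershed), filtered by a minimal pixel
#' count, and used as seeds to grow cell territories by watershed-style
#' propagation on the junction channel (boundaries settle on bright
#' junction ridges). Cells smaller than a minimal equivalent diameter or
#' not fully in frame are removed. Sphericity of the original 2.5D analysis
#' is rendered as 2D circularity 4*pi*A/P^2 (not identical; documented).
#'
#' @param nuclear_image,junction_image,icam_image registered 2D matrices.
#' @param pixel_size_um pixel size.
#' @param params named list overriding defaults: `nucleus_scale_um` (5),
#'   `nuc_threshold` (0.1), `min_nucleus_px` (173),
#'   `min_cell_diameter_um` (10.62).
#' @return data.frame with one row per kept cell: `cell`, `area_um2`,
#'   `circularity`, `icam_mean`, `x_px`, `y_px`.
#' @export
cell_morphometry <- function(nuclear_image, junction_image, icam_image,
                             pixel_size_um, params = list()) {
  p <- utils::modifyList(list(nucleus_scale_um = 5, nuc_threshold = 0.1,
                              min_nucleus_px = 173,
                              min_cell_diameter_um = 10.62), params)
  nuc <- as_matrix2d(nuclear_image)
  jun <- as_matrix2d(junction_image)
  icam <- as_matrix2d(icam_image)
  stopifnot(all(dim(nuc) == dim(jun)), all(dim(nuc) == dim(icam)))

  sigma <- p$nucleus_scale_um / pixel_size_um / 2
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(nuc), sigma = sigma))
  mask <- sm > p$nuc_threshold
  if (!any(mask)) {
    return(data.frame(cell = integer(0), area_um2 = numeric(0),
                      circularity = numeric(0), icam_mean = numeric(0),
                      x_px = numeric(0), y_px = numeric(0)))
  }
  seeds <- EBImage::imageData(EBImage::watershed(
    EBImage::distmap(EBImage::Image(mask * 1)), tolerance = 1))
  keep <- which(tabulate(seeds[seeds > 0]) >= p$min_nucleus_px)
  seeds[!(seeds %in% keep)] <- 0L
  seeds <- relabel(seeds)
  if (max(seeds) == 0) {
    return(data.frame(cell = integer(0), area_um2 = numeric(0),
                      circularity = numeric(0), icam_mean = numeric(0),
                      x_px = numeric(0), y_px = numeric(0)))
  }
  # cells grow from the nuclei but may not cross bright junction ridges;
  # the ridge pixels are then split between the adjacent cells so that the
  # junction's area share is not lost
  ridge <- matrix(FALSE, nrow(jun), ncol(jun))
  if (diff(range(jun)) > 0) {
    jn <- (jun - min(jun)) / diff(range(jun))
    ridge <- jn > EBImage::otsu(EBImage::Image(jn))
  }
  cells <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(jun), seeds = EBImage::Image(seeds),
    mask = EBImage::Image(!ridge | seeds > 0), lambda = 1e-4))
  if (any(ridge)) {
    cells <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(jun), seeds = EBImage::Image(cells),
      mask = EBImage::Image(ridge | cells > 0), lambda = 1e10))
  }
  cells <- matrix(as.integer(cells), nrow(cells), ncol(cells))

  min_d_px <- p$min_cell_diameter_um / pixel_size_um
  keep <- label_filter_diameter(cells, min_d_px, Inf)
  cells[!(cells %in% keep)] <- 0L
  cells <- drop_border_labels(cells)
  cells <- relabel(cells)
  ids <- seq_len(max(cells))
  if (length(ids) == 0) {
    return(data.frame(cell = integer(0), area_um2 = numeric(0),
                      circularity = numeric(0), icam_mean = numeric(0),
                      x_px = numeric(0), y_px = numeric(0)))
  }
  shp <- EBImage::computeFeatures.shape(cells)
  area_px <- shp[, "s.area"]
  perim <- shp[, "s.perimeter"]
  rows <- row(cells); cols <- col(cells)
  data.frame(
    cell = ids,
    area_um2 = area_px * pixel_size_um^2,
    circularity = pmin(1, 4 * pi * area_px / perim^2),
    icam_mean = vapply(ids, function(i) mean(icam[cells == i]), numeric(1)),
    x_px = vapply(ids, function(i) mean(cols[cells == i]) - 1, numeric(1)),
    y_px = vapply(ids, function(i) mean(rows[cells == i]) - 1, numeric(1))
  )
}
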