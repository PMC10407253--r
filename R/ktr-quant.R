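#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background of a single-channel frame by grayscale
#' morphological opening with a disc structuring element of the given radius
#' and subtracts it. Structures smaller than the disc (nuclei, spots) are
#' preserved; anything wider (illumination gradients) is removed. Output is
#' non-negative everywhere.
#'
#' @param image 2D numeric matrix.
#' @param radius_px structuring-element radius in pixels (default 50).
#' @return matrix of the same size, `image - opening(image)`.
#' @export
subtract_background <- function(image, radius_px = 50) {
  if (radius_px <= 0) stop("radius_px must be > 0")
  image <- as_matrix2d(image)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(image, brush))
  image - bg
}

as_matrix2d <- function(x) {
  x <- EBImage::imageData(EBImage::Image(x))
  if (length(dim(x)) != 2) stop("expected a single 2D frame")
  x
}

#' Segment nuclei from a nuclear-marker frame
#'
#' Global threshold on intensities scaled to `[0, 1]`, distance-transform
#' watershed declumping, then size selection by equivalent diameter and
#' removal of border-touching objects.
#'
#' @param nuclear_image 2D matrix, intensities in `[0, 1]`.
#' @param d_min_px,d_max_px accepted equivalent-diameter range in pixels
#'   (defaults 30 and 100).
#' @param threshold global manual threshold (default 0.1).
#' @param watershed_tolerance minimum distance-map depth between declumped
#'   objects.
#' @return integer label matrix; labels are consecutive from 1.
#' @export
segment_nuclei <- function(nuclear_image, d_min_px = 30, d_max_px = 100,
                           threshold = 0.1, watershed_tolerance = 1) {
  img <- as_matrix2d(nuclear_image)
  mask <- img > threshold
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance))
  keep <- label_filter_diameter(labels, d_min_px, d_max_px)
  labels[!(labels %in% keep)] <- 0L
  labels <- drop_border_labels(labels)
  relabel(labels)
}

label_filter_diameter <- function(labels, d_min, d_max) {
  tab <- tabulate(labels[labels > 0])
  eqd <- 2 * sqrt(tab / pi)
  which(eqd >= d_min & eqd <= d_max)
}

drop_border_labels <- function(labels) {
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  labels[labels %in% border[border > 0]] <- 0L
  labels
}

relabel <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- match(labels[labels > 0], ids)
  out
}

#' Segment cell bodies and cytoplasmic rings around nuclei
#'
#' Each cell is grown from its nucleus as a ring of at most `ring_px`
#' pixels, restricted to KTR signal above a global threshold; where rings of
#' neighbouring cells collide, pixels go to the nearest nucleus. The
#' cytoplasm of a cell is its cell area minus its nucleus.
#'
#' @param nuclei_labels integer label matrix from [segment_nuclei()].
#' @param ktr_image KTR-channel frame matching the labels, in `[0, 1]`.
#' @param ring_px maximal ring width in pixels (default 10).
#' @param threshold global manual KTR threshold (default 0.08).
#' @return list with `cells` and `cytoplasm` integer label matrices sharing
#'   the nucleus label ids, and `unmeasurable`, the ids of nuclei whose
#'   cytoplasm came out empty.
#' @export
segment_cytoplasm <- function(nuclei_labels, ktr_image, ring_px = 10,
                              threshold = 0.08) {
  ktr <- as_matrix2d(ktr_image)
  if (!all(dim(nuclei_labels) == dim(ktr))) {
    stop("nuclei_labels and ktr_image differ in shape")
  }
  if (max(nuclei_labels) == 0) {
    z <- matrix(0L, nrow(ktr), ncol(ktr))
    return(list(cells = z, cytoplasm = z, unmeasurable = integer(0)))
  }
  # distance of every pixel to the nearest nucleus pixel
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image((nuclei_labels == 0) * 1)))
  mask <- (d <= ring_px) & (ktr >= threshold | nuclei_labels > 0)
  # large lambda => propagation cost is dominated by geodesic distance,
  # i.e. collision pixels are split by the nearest-nucleus rule
  cells <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(ktr), seeds = EBImage::Image(nuclei_labels),
    mask = EBImage::Image(mask), lambda = 1e10))
  cells <- matrix(as.integer(cells), nrow(cells), ncol(cells))
  cyto <- cells
  cyto[nuclei_labels > 0] <- 0L
  ids <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  unmeasurable <- setdiff(ids, unique(cyto[cyto > 0]))
  list(cells = cells, cytoplasm = cyto, unmeasurable = unmeasurable)
}

#' Per-cell nuclear and cytoplasmic intensities and C/N ratio
#'
#' Mean KTR intensity over the nucleus (N) and cytoplasm (C) of every cell
#' and their ratio C/N, the kinase-activity readout. Cells where either
#' compartment has fewer than `min_pixels` pixels, or where N is zero, get
#' `NA` (missing, not zero).
#'
#' @param nuclei_labels,cytoplasm_labels matching integer label matrices.
#' @param ktr_image KTR-channel frame.
#' @param min_pixels minimal compartment size in pixels (default 20).
#' @return data.frame with `label`, `nuc_mean`, `cyto_mean`, `cn_ratio`,
#'   `nuc_px`, `cyto_px`, and the nucleus centroid `x_px`, `y_px`
#'   (0-based column / row).
#' @export
measure_cn <- function(nuclei_labels, cytoplasm_labels, ktr_image,
                       min_pixels = 20) {
  ktr <- as_matrix2d(ktr_image)
  ids <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  if (length(ids) == 0) {
    return(data.frame(label = integer(0), nuc_mean = numeric(0),
                      cyto_mean = numeric(0), cn_ratio = numeric(0),
                      nuc_px = integer(0), cyto_px = integer(0),
                      x_px = numeric(0), y_px = numeric(0)))
  }
  stat <- function(lab) {
    px <- tabulate(lab[lab > 0], nbins = max(ids))[ids]
    sums <- vapply(ids, function(i) sum(ktr[lab == i]), numeric(1))
    list(px = px, mean = ifelse(px > 0, sums / px, NA_real_))
  }
  ns <- stat(nuclei_labels)
  cs <- stat(cytoplasm_labels)
  rows <- row(nuclei_labels); cols <- col(nuclei_labels)
  cy <- vapply(ids, function(i) mean(rows[nuclei_labels == i]), numeric(1))
  cx <- vapply(ids, function(i) mean(cols[nuclei_labels == i]), numeric(1))
  ok <- ns$px >= min_pixels & cs$px >= min_pixels &
    !is.na(ns$mean) & ns$mean > 0
  data.frame(label = ids,
             nuc_mean = ifelse(ok, ns$mean, NA_real_),
             cyto_mean = ifelse(ok, cs$mean, NA_real_),
             cn_ratio = ifelse(ok, cs$mean / ns$mean, NA_real_),
             nuc_px = ns$px, cyto_px = cs$px,
             x_px = cx - 1, y_px = cy - 1)
}

#' Link objects across frames by mask overlap
#'
#' Objects in consecutive frames are linked when their masks overlap and
#' their centroids moved at most `max_disp_px` pixels. Among competing
#' candidates the largest overlap wins (ties: smaller displacement, then
#' lower label id). Unlinked objects start new tracks; tracks are never
#' merged. With `require_overlap = FALSE` the overlap condition is dropped
#' and linking falls back to pure centroid distance (sparse scenes).
#'
#' @param labels_list list of integer label matrices, one per frame.
#' @param max_disp_px maximum centroid displacement per frame (default 3).
#' @param require_overlap require mask overlap in addition to the
#'   displacement gate (default TRUE).
#' @return data.frame with `frame` (0-based), `label`, `track_id`.
#' @export
track_overlap <- function(labels_list, max_disp_px = 3, require_overlap = TRUE) {
  nT <- length(labels_list)
  stopifnot(nT >= 1)
  cents <- lapply(labels_list, label_centroids)
  out <- vector("list", nT)
  prev_tracks <- NULL
  next_track <- 1L
  for (f in seq_len(nT)) {
    ids <- cents[[f]]$label
    track <- rep(NA_integer_, length(ids))
    if (f > 1 && length(ids) > 0 && nrow(cents[[f - 1]]) > 0) {
      cand <- link_candidates(labels_list[[f - 1]], labels_list[[f]],
                              cents[[f - 1]], cents[[f]],
                              max_disp_px, require_overlap)
      if (nrow(cand) > 0) {
        cand <- cand[order(-cand$overlap, cand$disp, cand$prev, cand$cur), ]
        used_prev <- used_cur <- integer(0)
        for (k in seq_len(nrow(cand))) {
          p <- cand$prev[k]; q <- cand$cur[k]
          if (p %in% used_prev || q %in% used_cur) next
          track[match(q, ids)] <-
            prev_tracks$track[match(p, prev_tracks$label)]
          used_prev <- c(used_prev, p); used_cur <- c(used_cur, q)
        }
      }
    }
    for (k in which(is.na(track))) {
      track[k] <- next_track
      next_track <- next_track + 1L
    }
    out[[f]] <- data.frame(frame = f - 1L, label = ids, track_id = track)
    prev_tracks <- data.frame(label = ids, track = track)
  }
  do.call(rbind, out)
}

label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  }
  rows <- row(labels); cols <- col(labels)
  data.frame(
    label = ids,
    row = vapply(ids, function(i) mean(rows[labels == i]), numeric(1)),
    col = vapply(ids, function(i) mean(cols[labels == i]), numeric(1))
  )
}

link_candidates <- function(prev_lab, cur_lab, prev_c, cur_c,
                            max_disp, require_overlap) {
  if (require_overlap) {
    both <- prev_lab > 0 & cur_lab > 0
    if (!any(both)) return(data.frame(prev = integer(0), cur = integer(0),
                                      overlap = integer(0), disp = numeric(0)))
    tab <- table(prev = prev_lab[both], cur = cur_lab[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    cand <- data.frame(prev = as.integer(df$prev), cur = as.integer(df$cur),
                       overlap = df$Freq)
  } else {
    cand <- expand.grid(prev = prev_c$label, cur = cur_c$label)
    cand$overlap <- 0L
  }
  pi <- match(cand$prev, prev_c$label)
  ci <- match(cand$cur, cur_c$label)
  cand$disp <- sqrt((prev_c$row[pi] - cur_c$row[ci])^2 +
                    (prev_c$col[pi] - cur_c$col[ci])^2)
  cand[cand$disp <= max_disp, , drop = FALSE]
}

#' Full KTR quantification pipeline
#'
#' Per frame: background-subtract the nuclear channel, segment nuclei,
#' grow cytoplasmic rings on the KTR channel, measure N, C and C/N; then
#' link nuclei across frames by overlap tracking. Emits one row per
#' (track, frame) over each track's full [first, last] frame span, with
#' `present = FALSE` rows (NA measurements) where a tracked cell was not
#' measurable in a frame.
#'
#' @param nuclear_stack,ktr_stack H x W x T numeric arrays, same shape,
#'   intensities in `[0, 1]`.
#' @param config named list overriding defaults: `bg_radius_px` (50),
#'   `d_min_px` (30), `d_max_px` (100), `nuc_threshold` (0.1), `ring_px`
#'   (10), `cyto_threshold` (0.08), `min_pixels` (20), `max_disp_px` (3),
#'   `require_overlap` (TRUE), `frame_interval_s` (30).
#' @return data.frame with columns `track_id`, `frame` (0-based), `time_s`,
#'   `nuc_mean`, `cyto_mean`, `cn_ratio`, `x_px`, `y_px`, `present`.
#' @export
run_ktr_pipeline <- function(nuclear_stack, ktr_stack, config = list()) {
  cfg <- utils::modifyList(list(
    bg_radius_px = 50, d_min_px = 30, d_max_px = 100, nuc_threshold = 0.1,
    ring_px = 10, cyto_threshold = 0.08, min_pixels = 20, max_disp_px = 3,
    require_overlap = TRUE, frame_interval_s = 30
  ), config)
  if (length(dim(nuclear_stack)) == 2) {
    nuclear_stack <- array(nuclear_stack, c(dim(nuclear_stack), 1))
  }
  if (length(dim(ktr_stack)) == 2) {
    ktr_stack <- array(ktr_stack, c(dim(ktr_stack), 1))
  }
  stopifnot(all(dim(nuclear_stack) == dim(ktr_stack)))
  nT <- dim(nuclear_stack)[3]
  if (nT == 0) stop("empty stack")

  labels_list <- vector("list", nT)
  meas <- vector("list", nT)
  for (f in seq_len(nT)) {
    nb <- subtract_background(nuclear_stack[, , f], cfg$bg_radius_px)
    nl <- segment_nuclei(nb, cfg$d_min_px, cfg$d_max_px, cfg$nuc_threshold)
    seg <- segment_cytoplasm(nl, ktr_stack[, , f], cfg$ring_px, cfg$cyto_threshold)
    labels_list[[f]] <- nl
    m <- measure_cn(nl, seg$cytoplasm, ktr_stack[, , f], cfg$min_pixels)
    if (nrow(m) > 0) m$frame <- f - 1L
    meas[[f]] <- m
  }
  if (all(vapply(labels_list, max, numeric(1)) == 0)) {
    stop(sprintf(
      "segmentation found no nuclei in any of %d frames (nuc_threshold = %g, d_min_px = %g): check intensity scaling",
      nT, cfg$nuc_threshold, cfg$d_min_px))
  }
  tracks <- track_overlap(labels_list, cfg$max_disp_px, cfg$require_overlap)
  meas <- do.call(rbind, meas[vapply(meas, nrow, integer(1)) > 0])
  tab <- merge(tracks, meas, by = c("frame", "label"), all.x = TRUE)
  tab$present <- !is.na(tab$cn_ratio)

  # complete each track over its frame span
  spans <- split(tab, tab$track_id)
  full <- lapply(spans, function(d) {
    fr <- min(d$frame):max(d$frame)
    out <- d[match(fr, d$frame), ]
    out$frame <- fr
    out$track_id <- d$track_id[1]
    out$present[is.na(out$present)] <- FALSE
    out
  })
  tab <- do.call(rbind, full)
  tab$time_s <- tab$frame * cfg$frame_interval_s
  rownames(tab) <- NULL
  tab[order(tab$track_id, tab$frame),
      c("track_id", "frame", "time_s", "nuc_mean", "cyto_mean",
        "cn_ratio", "x_px", "y_px", "present")]
}
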