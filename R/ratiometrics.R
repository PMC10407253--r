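#' FRET ratio trace (acceptor / donor) within ROI masks
#'
#' Per frame, the ratio of the mean acceptor to the mean donor intensity
#' within each ROI mask — the Venus/Cerulean3 readout of a ratiometric
#' biosensor. The common use is a whole-cell mask paired with a sub-ROI
#' (the area directly under a crawling neutrophil) measured on the same
#' time point.
#'
#' @param acceptor_stack,donor_stack registered H x W x T arrays.
#' @param masks named list of masks; each a logical H x W matrix (static
#'   ROI) or H x W x T array (per-frame ROI).
#' @param frame_interval_s optional seconds per frame.
#' @return data.frame with `frame` (0-based), `roi`, `ratio` (and `time_s`
#'   if the interval is given).
#' @export
fret_ratio_trace <- function(acceptor_stack, donor_stack, masks,
                             frame_interval_s = NULL) {
  stopifnot(all(dim(acceptor_stack) == dim(donor_stack)), length(masks) > 0)
  if (is.null(names(masks))) names(masks) <- paste0("roi", seq_along(masks))
  nT <- dim(acceptor_stack)[3]
  out <- do.call(rbind, lapply(names(masks), function(nm) {
    mk <- masks[[nm]]
    ratio <- vapply(seq_len(nT), function(f) {
      m <- if (length(dim(mk)) == 3) mk[, , f] else mk
      dn <- mean(donor_stack[, , f][m])
      if (!is.finite(dn) || dn == 0) stop("donor mean is 0 in ROI '", nm, "'")
      mean(acceptor_stack[, , f][m]) / dn
    }, numeric(1))
    data.frame(frame = seq_len(nT) - 1L, roi = nm, ratio = ratio)
  }))
  if (!is.null(frame_interval_s)) out$time_s <- out$frame * frame_interval_s
  rownames(out) <- NULL
  out
}

#' Two-point FRAP recovery normalization
#'
#' Rescales a photobleaching trace so that the pre-bleach anchor reads
#' exactly 100% and the post-bleach anchor exactly 0%:
#' `100 * (I(t) - I(t_bleach)) / (I(t_prebleach) - I(t_bleach))`. Anchors
#' are taken at the sampled frames nearest the stated times. The
#' single-anchor variant (`anchor = "first_frame"`) instead divides by the
#' first frame only (100% there, bleach depth retained in the curve).
#'
#' @param trace data.frame with `time_s` and `value`.
#' @param t_prebleach_s,t_bleach_s anchor times (defaults 0 and 15).
#' @param anchor `"two_point"` (default) or `"first_frame"`.
#' @return data.frame `time_s`, `percent`.
#' @export
frap_normalize <- function(trace, t_prebleach_s = 0, t_bleach_s = 15,
                           anchor = c("two_point", "first_frame")) {
  anchor <- match.arg(anchor)
  stopifnot(all(c("time_s", "value") %in% names(trace)), nrow(trace) >= 2)
  if (anchor == "first_frame") {
    i0 <- trace$value[which.min(trace$time_s)]
    if (i0 == 0) stop("first-frame intensity is 0")
    return(data.frame(time_s = trace$time_s, percent = 100 * trace$value / i0))
  }
  if (max(trace$time_s) < t_bleach_s || min(trace$time_s) > t_prebleach_s) {
    stop("trace does not cover both anchor times")
  }
  ip <- trace$value[which.min(abs(trace$time_s - t_prebleach_s))]
  ib <- trace$value[which.min(abs(trace$time_s - t_bleach_s))]
  if (ip == ib) stop("anchor intensities are equal: cannot normalize")
  data.frame(time_s = trace$time_s,
             percent = 100 * (trace$value - ib) / (ip - ib))
}

#' Fluorophore crosstalk matrix from single-colour acquisitions
#'
#' For each fluorophore, transfected alone and imaged in every channel with
#' identical settings, an ROI is chosen on its own channel (the brightest
#' cell: the connected component above the Otsu threshold with the highest
#' mean) and reused across channels. Entry (i, j) is the fluorophore-i
#' signal in channel j divided by its signal in its own channel i, so the
#' diagonal is exactly 1.
#'
#' @param single_color_stacks named list, one element per fluorophore:
#'   an H x W x n_channels array (channel order identical across
#'   fluorophores and matching the list order).
#' @return square numeric matrix with fluorophores as rows and channels as
#'   columns; attribute `rois` holds the ROI masks.
#' @export
crosstalk_matrix <- function(single_color_stacks) {
  n <- length(single_color_stacks)
  stopifnot(n >= 1)
  nm <- names(single_color_stacks)
  if (is.null(nm)) nm <- paste0("fp", seq_len(n))
  M <- matrix(NA_real_, n, n, dimnames = list(fluorophore = nm, channel = nm))
  rois <- vector("list", n); names(rois) <- nm
  for (i in seq_len(n)) {
    stack <- single_color_stacks[[i]]
    stopifnot(dim(stack)[3] == n)
    roi <- brightest_cell_roi(stack[, , i])
    rois[[i]] <- roi
    own <- mean(stack[, , i][roi])
    if (own == 0) stop("own-channel signal is 0 for fluorophore '", nm[i], "'")
    for (j in seq_len(n)) M[i, j] <- mean(stack[, , j][roi]) / own
    M[i, i] <- 1
  }
  structure(M, rois = rois)
}

# brightest cell: connected component above Otsu with the highest mean
brightest_cell_roi <- function(img) {
  img <- as_matrix2d(img)
  rng <- range(img)
  if (diff(rng) == 0) stop("flat image: no cell to pick an ROI from")
  scaled <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled))
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(scaled > th)))
  ids <- seq_len(max(labels))
  means <- vapply(ids, function(k) mean(img[labels == k]), numeric(1))
  labels == ids[which.max(means)]
}
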