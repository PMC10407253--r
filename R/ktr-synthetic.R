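#' Scene specification for synthetic KTR time-lapses
#'
#' Describes the imaging geometry and timing of a synthetic kinase
#' translocation reporter (KTR) acquisition: a monolayer of endothelial-like
#' cells imaged in two channels (nuclear marker + KTR) at fixed intervals,
#' with a stimulus (neutrophil addition) at a known frame.
#'
#' Defaults mirror a confocal KTR acquisition: 512 x 512 px at
#' 0.33 um/px, 30 frames every 30 s (15 min total) with the stimulus at
#' frame 5 (2.5 min).
#'
#' @param field_size_px integer length-2, image height and width in pixels.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param n_cells number of cells to place in the field.
#' @param nucleus_diameter_px length-2 numeric range of nucleus diameters
#'   (pixels); each cell draws its diameter uniformly from this range.
#' @param cell_diameter_px cell (cytoplasm disk) diameter in pixels; must
#'   exceed the largest nucleus diameter.
#' @param frame_interval_s time between frames, seconds.
#' @param n_frames number of frames.
#' @param stimulus_frame 0-based frame index at which the stimulus is added;
#'   frames `0 .. stimulus_frame - 1` are baseline.
#' @param seed integer seed controlling cell placement and noise.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(field_size_px = c(512L, 512L),
                       pixel_size_um = 0.33,
                       n_cells = 20L,
                       nucleus_diameter_px = c(32, 40),
                       cell_diameter_px = 60,
                       frame_interval_s = 30,
                       n_frames = 30L,
                       stimulus_frame = 5L,
                       seed = 1L) {
  stopifnot(length(field_size_px) == 2, all(field_size_px > 0))
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (length(nucleus_diameter_px) == 1) {
    nucleus_diameter_px <- rep(nucleus_diameter_px, 2)
  }
  if (max(nucleus_diameter_px) >= cell_diameter_px) {
    stop("nucleus_diameter_px must be smaller than cell_diameter_px")
  }
  if (stimulus_frame >= n_frames) stop("stimulus_frame must be < n_frames")
  if (stimulus_frame < 1) stop("stimulus_frame must be >= 1 (need baseline frames)")
  structure(list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    n_cells = as.integer(n_cells),
    nucleus_diameter_px = nucleus_diameter_px,
    cell_diameter_px = cell_diameter_px,
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    stimulus_frame = as.integer(stimulus_frame),
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Condition presets for the KTR generative model
#'
#' The two study conditions: `"control"` monolayers in which about 5% of
#' cells show elevated kinase activity, and `"neutrophil"` monolayers in
#' which the fraction of responding cells rises to 50%. Both presets share
#' the response kinetics; only the responder rate differs.
#'
#' The responder count in any generated sample is exact,
#' `round(responder_rate * n_cells)`, never binomially sampled, so that
#' downstream fraction estimates are not confounded by sampling noise.
#'
#' @param name `"control"` or `"neutrophil"`.
#' @param responder_rate fraction of responding cells; defaults to 0.05
#'   (control) or 0.50 (neutrophil).
#' @param amplitude C/N-ratio amplitude of the response plateau.
#' @param rise_tau_frames exponential rise time constant, in frames.
#' @param rise_delay_frames lag between the stimulus frame and the onset of
#'   translocation, in frames.
#' @param noise_sd i.i.d. Gaussian noise on the C/N readout, C/N units.
#' @param baseline_cn length-2 range of per-cell baseline C/N levels.
#' @return A list of class `"ktr_preset"`.
#' @export
ktr_preset <- function(name = c("control", "neutrophil"),
                       responder_rate = NULL,
                       amplitude = 0.4,
                       rise_tau_frames = 2,
                       rise_delay_frames = 1,
                       noise_sd = 0.05,
                       baseline_cn = c(0.9, 1.1)) {
  name <- match.arg(name)
  if (is.null(responder_rate)) {
    responder_rate <- switch(name, control = 0.05, neutrophil = 0.50)
  }
  stopifnot(responder_rate >= 0, responder_rate <= 1,
            rise_tau_frames > 0, noise_sd >= 0)
  if (length(baseline_cn) == 1) baseline_cn <- rep(baseline_cn, 2)
  structure(list(
    name = name,
    responder_rate = responder_rate,
    amplitude = amplitude,
    rise_tau_frames = rise_tau_frames,
    rise_delay_frames = rise_delay_frames,
    noise_sd = noise_sd,
    baseline_cn = baseline_cn
  ), class = "ktr_preset")
}

# Latent activity a(t) in C/N units for one cell: zero before onset, then
# amplitude * (1 - exp(-dt / tau)) with dt counted from stimulus + delay.
ktr_activity_trace <- function(preset, n_frames, stimulus_frame, responder) {
  t <- seq_len(n_frames) - 1L
  if (!responder) return(numeric(n_frames))
  onset <- stimulus_frame + preset$rise_delay_frames
  dt <- pmax(t - onset, 0)
  ifelse(t >= onset, preset$amplitude * (1 - exp(-dt / preset$rise_tau_frames)), 0)
}

#' Generate synthetic C/N traces directly from the generative model
#'
#' Fast path that bypasses image rendering: per-cell cytoplasm/nucleus (C/N)
#' ratio traces are drawn as `baseline + activity + noise`, where a fixed
#' number `round(responder_rate * n_cells)` of cells respond to the stimulus
#' with an exponential-rise step and the rest stay at baseline.
#'
#' @param n_cells number of cells (rows).
#' @param preset a [ktr_preset()].
#' @param n_frames number of frames (columns).
#' @param stimulus_frame 0-based stimulus frame index.
#' @param seed integer seed; identical arguments give identical output.
#' @return list with `cn` (n_cells x n_frames matrix of C/N ratios; columns
#'   named `f0, f1, ...` for 0-based frames), `truth` (data.frame with
#'   `cell`, `responder`, `baseline`), `activity` (noise-free latent
#'   activity matrix, C/N units), `stimulus_frame`, `preset`.
#' @export
gen_traces <- function(n_cells, preset, n_frames = 30L, stimulus_frame = 5L,
                       seed = 1L) {
  stopifnot(inherits(preset, "ktr_preset"), n_cells >= 1,
            stimulus_frame >= 1, stimulus_frame < n_frames)
  set.seed(seed)
  n_resp <- round(preset$responder_rate * n_cells)
  responder <- logical(n_cells)
  responder[sample.int(n_cells, n_resp)] <- TRUE
  baseline <- runif(n_cells, preset$baseline_cn[1], preset$baseline_cn[2])
  activity <- t(vapply(
    responder,
    function(r) ktr_activity_trace(preset, n_frames, stimulus_frame, r),
    numeric(n_frames)
  ))
  noise <- matrix(rnorm(n_cells * n_frames, sd = preset$noise_sd),
                  n_cells, n_frames)
  cn <- baseline + activity + noise
  dimnames(cn) <- list(paste0("cell", seq_len(n_cells)),
                       paste0("f", seq_len(n_frames) - 1L))
  dimnames(activity) <- dimnames(cn)
  list(cn = cn,
       truth = data.frame(cell = seq_len(n_cells), responder = responder,
                          baseline = baseline),
       activity = activity,
       stimulus_frame = as.integer(stimulus_frame),
       preset = preset)
}

# Digital disk mask indices on an H x W grid; centre in (row, col), 1-based.
disk_pixels <- function(h, w, cr, cc, diameter) {
  r2 <- (diameter / 2)^2
  rr <- max(1L, floor(cr - diameter / 2)):min(h, ceiling(cr + diameter / 2))
  cc_ <- max(1L, floor(cc - diameter / 2)):min(w, ceiling(cc + diameter / 2))
  grid <- expand.grid(row = rr, col = cc_)
  keep <- (grid$row - cr)^2 + (grid$col - cc)^2 <= r2
  cbind(row = grid$row[keep], col = grid$col[keep])
}

place_cells <- function(spec, margin, min_dist) {
  h <- spec$field_size_px[1]; w <- spec$field_size_px[2]
  if (2 * margin >= min(h, w)) stop("field too small for cell diameter")
  centers <- matrix(NA_real_, spec$n_cells, 2)
  max_tries <- 200L * spec$n_cells + 200L
  tries <- 0L
  placed <- 0L
  while (placed < spec$n_cells) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "could not place %d non-overlapping cells of diameter %g px in a %d x %d field: density limit exceeded",
        spec$n_cells, spec$cell_diameter_px, h, w))
    }
    cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    if (placed > 0) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_dist^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- round(cand)
  }
  centers
}

#' Render a synthetic two-channel KTR movie with ground truth
#'
#' Renders non-overlapping cells as disks (cytoplasm) with concentric disk
#' nuclei. The KTR channel redistributes a constant per-cell total signal
#' between nucleus and cytoplasm so that the mean-intensity C/N ratio of
#' each cell follows the latent activity trace exactly; the nuclear-marker
#' channel shows only nuclei. Gaussian read noise and a smooth background
#' gradient are added with amplitudes proportional to the preset's
#' `noise_sd`, so a zero-noise preset yields an exactly clean movie.
#'
#' @param spec a [scene_spec()].
#' @param preset a [ktr_preset()].
#' @param read_noise_sd per-pixel Gaussian noise sd (intensity units);
#'   default scales with the preset noise.
#' @param bg_amplitude peak amplitude of a smooth diagonal background
#'   gradient added to both channels; default scales with the preset noise.
#' @param drift_px_per_frame length-2 (row, col) translation applied to
#'   every cell per frame; used to exercise tracking.
#' @param nuclear_level nuclear-marker disk intensity.
#' @param ktr_level mean KTR intensity a cell would have at C/N = 1.
#' @return list with `nuclear` and `ktr` (H x W x T arrays, intensities in
#'   `[0, 1]`-ish arbitrary units), and `truth` containing the per-cell
#'   placement table (`cell`, `responder`, `row`, `col`, `nucleus_d`,
#'   `cell_d`), the analytic `cn` matrix, per-frame centroids, the spec and
#'   preset.
#' @export
gen_ktr_movie <- function(spec, preset,
                          read_noise_sd = 0.2 * preset$noise_sd,
                          bg_amplitude = preset$noise_sd,
                          drift_px_per_frame = c(0, 0),
                          nuclear_level = 0.5,
                          ktr_level = 0.4) {
  stopifnot(inherits(spec, "scene_spec"), inherits(preset, "ktr_preset"))
  h <- spec$field_size_px[1]; w <- spec$field_size_px[2]
  n <- spec$n_cells; nT <- spec$n_frames
  total_drift <- abs(drift_px_per_frame) * (nT - 1)

  # traces first (consumes the seed stream deterministically), then placement
  tr <- gen_traces(n, preset, nT, spec$stimulus_frame, seed = spec$seed)
  nuc_d <- runif(n, spec$nucleus_diameter_px[1], spec$nucleus_diameter_px[2])
  margin <- spec$cell_diameter_px / 2 + 12 + max(total_drift)
  centers <- place_cells(spec, margin = margin,
                         min_dist = spec$cell_diameter_px + 2)

  bg <- bg_amplitude *
    (outer(seq(0, 1, length.out = h), seq(0, 1, length.out = w), `+`) / 2)
  nuclear <- array(0, c(h, w, nT))
  ktr <- array(0, c(h, w, nT))
  cent <- array(NA_real_, c(n, 2, nT), dimnames = list(NULL, c("row", "col"), NULL))

  for (f in seq_len(nT)) {
    nuc_f <- matrix(0, h, w)
    ktr_f <- matrix(0, h, w)
    off <- drift_px_per_frame * (f - 1)
    for (i in seq_len(n)) {
      cr <- centers[i, 1] + off[1]; cc <- centers[i, 2] + off[2]
      cent[i, , f] <- c(cr, cc)
      npx <- disk_pixels(h, w, cr, cc, nuc_d[i])
      cpx <- disk_pixels(h, w, cr, cc, spec$cell_diameter_px)
      in_nuc <- paste(cpx[, 1], cpx[, 2]) %in% paste(npx[, 1], npx[, 2])
      an <- nrow(npx); ac <- sum(!in_nuc)
      r <- tr$cn[i, f]
      # constant total per cell: translocation conserves signal
      total <- ktr_level * (an + ac)
      n_mean <- total / (an + r * ac)
      c_mean <- r * n_mean
      nuc_f[npx] <- nuclear_level
      ktr_f[npx] <- n_mean
      ktr_f[cpx[!in_nuc, , drop = FALSE]] <- c_mean
    }
    nuc_f <- nuc_f + bg
    ktr_f <- ktr_f + bg
    if (read_noise_sd > 0) {
      nuc_f <- nuc_f + matrix(rnorm(h * w, sd = read_noise_sd), h, w)
      ktr_f <- ktr_f + matrix(rnorm(h * w, sd = read_noise_sd), h, w)
    }
    nuclear[, , f] <- pmax(nuc_f, 0)
    ktr[, , f] <- pmax(ktr_f, 0)
  }

  truth <- tr$truth
  truth$row <- centers[, 1]; truth$col <- centers[, 2]
  truth$nucleus_d <- nuc_d; truth$cell_d <- spec$cell_diameter_px
  list(nuclear = nuclear, ktr = ktr,
       truth = list(cells = truth, cn = tr$cn, activity = tr$activity,
                    centroids = cent, spec = spec, preset = preset))
}
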