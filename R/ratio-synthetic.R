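#' Generate synthetic FRAP, FRET and crosstalk inputs
#'
#' Umbrella generator for the ratiometric module's test inputs, dispatching
#' on `kind`:
#'
#' * `"frap"` — an intensity trace with a pre-bleach plateau, an
#'   instantaneous drop at the bleach time and an exponential recovery to a
#'   stated fraction of the lost signal (see [gen_frap_trace()]).
#' * `"fret"` — paired donor/acceptor traces whose ratio steps by a stated
#'   factor at a stated frame (see [gen_fret_traces()]).
#' * `"crosstalk"` — one multi-channel stack per fluorophore with stated
#'   bleed-through fractions into the other channels (see
#'   [gen_crosstalk_stacks()]).
#'
#' @param kind `"frap"`, `"fret"` or `"crosstalk"`.
#' @param params named list passed to the specific generator.
#' @param seed integer seed.
#' @return the specific generator's value.
#' @export
gen_ratiometric_traces <- function(kind = c("frap", "fret", "crosstalk"),
                                   params = list(), seed = 1L) {
  kind <- match.arg(kind)
  fn <- switch(kind, frap = gen_frap_trace, fret = gen_fret_traces,
               crosstalk = gen_crosstalk_stacks)
  do.call(fn, c(params, list(seed = seed)))
}

#' Synthetic FRAP trace
#'
#' `I(t) = I0` before the bleach; at and after the bleach
#' `I(t) = Ib + f (I0 - Ib) (1 - exp(-(t - t_bleach)/tau))` with
#' `Ib = I0 (1 - bleach_depth)`. Under the two-point normalization the
#' curve starts at 100, hits 0 at the bleach anchor and plateaus at
#' `100 * recovery_fraction`.
#'
#' @param duration_s,dt_s acquisition length and sampling interval
#'   (defaults 600 and 5: ten minutes every five seconds).
#' @param bleach_time_s bleach time (default 15; the two-point anchors
#'   0 s / 15 s then fall on sampled frames).
#' @param bleach_depth fraction of signal removed by the bleach
#'   (default 1).
#' @param recovery_fraction mobile fraction `f` in `[0, 1]` (default 0.7).
#' @param tau_s recovery time constant (default 30).
#' @param i0 pre-bleach intensity (default 1).
#' @param noise_sd additive Gaussian noise (default 0).
#' @param seed integer seed.
#' @return data.frame `time_s`, `value`.
#' @export
gen_frap_trace <- function(duration_s = 600, dt_s = 5, bleach_time_s = 15,
                           bleach_depth = 1, recovery_fraction = 0.7,
                           tau_s = 30, i0 = 1, noise_sd = 0, seed = 1L) {
  stopifnot(bleach_depth > 0, bleach_depth <= 1,
            recovery_fraction >= 0, recovery_fraction <= 1, tau_s > 0)
  set.seed(seed)
  t <- seq(0, duration_s, by = dt_s)
  ib <- i0 * (1 - bleach_depth)
  v <- ifelse(t < bleach_time_s, i0,
              ib + recovery_fraction * (i0 - ib) *
                (1 - exp(-(t - bleach_time_s) / tau_s)))
  if (noise_sd > 0) v <- v + rnorm(length(v), sd = noise_sd)
  data.frame(time_s = t, value = v)
}

#' Synthetic FRET donor/acceptor trace pair
#'
#' Constant donor; the acceptor/donor ratio is `ratio0` before
#' `step_frame` and `ratio0 * step_factor` from it on.
#'
#' @param n_frames,dt_s frames and interval (defaults 30 and 5).
#' @param step_frame 0-based frame of the activity step (default 10).
#' @param step_factor fold change of the ratio (default 1.5).
#' @param ratio0 initial ratio (default 1).
#' @param donor_level donor intensity (default 1).
#' @param noise_sd multiplicative-free additive noise on both channels
#'   (default 0).
#' @param seed integer seed.
#' @return data.frame `frame` (0-based), `time_s`, `donor`, `acceptor`.
#' @export
gen_fret_traces <- function(n_frames = 30, dt_s = 5, step_frame = 10,
                            step_factor = 1.5, ratio0 = 1, donor_level = 1,
                            noise_sd = 0, seed = 1L) {
  set.seed(seed)
  fr <- seq_len(n_frames) - 1L
  ratio <- ratio0 * ifelse(fr >= step_frame, step_factor, 1)
  donor <- rep(donor_level, n_frames)
  acceptor <- donor * ratio
  if (noise_sd > 0) {
    donor <- donor + rnorm(n_frames, sd = noise_sd)
    acceptor <- acceptor + rnorm(n_frames, sd = noise_sd)
  }
  data.frame(frame = fr, time_s = fr * dt_s, donor = donor,
             acceptor = acceptor)
}

#' Synthetic FRET movie (uniform cell on dark background)
#'
#' Renders the traces of [gen_fret_traces()] as two image stacks with a
#' disk-shaped cell, for exercising [fret_ratio_trace()] end to end.
#'
#' @param size image side, pixels (default 64).
#' @param cell_radius_px cell disk radius (default 20).
#' @param ... passed to [gen_fret_traces()].
#' @return list with `acceptor`, `donor` (size x size x T arrays), `mask`
#'   (logical), `traces` (the generating table).
#' @export
gen_fret_stacks <- function(size = 64, cell_radius_px = 20, ...) {
  tr <- gen_fret_traces(...)
  nT <- nrow(tr)
  ctr <- (size + 1) / 2
  mask <- (row(matrix(0, size, size)) - ctr)^2 +
    (col(matrix(0, size, size)) - ctr)^2 <= cell_radius_px^2
  acceptor <- array(0, c(size, size, nT))
  donor <- array(0, c(size, size, nT))
  for (f in seq_len(nT)) {
    a <- matrix(0, size, size); d <- matrix(0, size, size)
    a[mask] <- tr$acceptor[f]; d[mask] <- tr$donor[f]
    acceptor[, , f] <- a; donor[, , f] <- d
  }
  list(acceptor = acceptor, donor = donor, mask = mask, traces = tr)
}

#' Synthetic single-colour stacks with known bleed-through
#'
#' For each fluorophore, a multi-channel acquisition of a single
#' transfected cell: full signal in its own channel and stated fractions
#' bled into the others. A dimmer second cell is added so that the
#' brightest-cell ROI choice is exercised.
#'
#' @param bleed square matrix of bleed fractions; entry (i, j) is the
#'   fraction of fluorophore i's signal appearing in channel j (diagonal
#'   forced to 1). Row/column names name the fluorophores.
#' @param size image side, pixels (default 64).
#' @param amplitude peak cell intensity (default 0.8).
#' @param dim_factor intensity of the decoy second cell relative to the
#'   main one (default 0.4).
#' @param noise_sd additive Gaussian noise (default 0).
#' @param seed integer seed.
#' @return named list of H x W x n arrays, one per fluorophore.
#' @export
gen_crosstalk_stacks <- function(bleed, size = 64, amplitude = 0.8,
                                 dim_factor = 0.4, noise_sd = 0, seed = 1L) {
  bleed <- as.matrix(bleed)
  n <- nrow(bleed)
  stopifnot(ncol(bleed) == n, all(bleed >= 0))
  diag(bleed) <- 1
  nm <- rownames(bleed)
  if (is.null(nm)) nm <- paste0("fp", seq_len(n))
  set.seed(seed)
  out <- vector("list", n); names(out) <- nm
  for (i in seq_len(n)) {
    # main cell and a dimmer decoy, both disks
    base <- matrix(0, size, size)
    ctr <- c(size * 0.35, size * 0.35)
    dec <- c(size * 0.7, size * 0.7)
    rr <- row(base); cc <- col(base)
    main <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= (size * 0.15)^2
    decoy <- (rr - dec[1])^2 + (cc - dec[2])^2 <= (size * 0.12)^2
    base[main] <- amplitude
    base[decoy] <- amplitude * dim_factor
    stack <- array(0, c(size, size, n))
    for (j in seq_len(n)) {
      ch <- bleed[i, j] * base
      if (noise_sd > 0) ch <- pmax(ch + matrix(rnorm(size^2, sd = noise_sd), size, size), 0)
      stack[, , j] <- ch
    }
    out[[i]] <- stack
  }
  out
}
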