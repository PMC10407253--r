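#' Signed nearest-neighbour distance to target surfaces or points
#'
#' Euclidean distance of each query point to the nearest target. When
#' targets are modelled as disks (`target_radius_um > 0`, the rendered
#' "surface" of a first-wave neutrophil), the distance is measured to the
#' disk surface and is negative for query points inside a disk. With point
#' targets the plain nearest-point distance is returned (never negative).
#'
#' @param query data.frame or matrix with `x_um`, `y_um` (or two columns).
#' @param targets same format; must be non-empty.
#' @param target_radius_um surface radius around each target centre
#'   (default 0 = point targets).
#' @return numeric vector of distances in micrometres, one per query point.
#' @export
signed_nn_distance <- function(query, targets, target_radius_um = 0) {
  q <- as_xy(query); tg <- as_xy(targets)
  if (nrow(tg) == 0) stop("target set is empty")
  if (nrow(q) == 0) return(numeric(0))
  d <- vapply(seq_len(nrow(q)), function(i) {
    min(sqrt((tg[, 1] - q[i, 1])^2 + (tg[, 2] - q[i, 2])^2))
  }, numeric(1))
  if (target_radius_um > 0) d - target_radius_um else d
}

as_xy <- function(p) {
  p <- as.data.frame(p)
  if (all(c("x_um", "y_um") %in% names(p))) {
    cbind(p$x_um, p$y_um)
  } else {
    as.matrix(p[, 1:2])
  }
}

#' Uniform random-dot null point set
#'
#' Draws `n` i.i.d. uniform points over the field, the null model matched
#' in number to the observed second wave.
#'
#' @param n number of points (>= 0).
#' @param field length-2 field size (width, height) in micrometres, or
#'   length-4 bounds `(xmin, xmax, ymin, ymax)`.
#' @param seed integer seed (optional).
#' @return data.frame with `x_um`, `y_um`.
#' @export
random_dot_null <- function(n, field, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  b <- if (length(field) == 4) field else c(0, field[1], 0, field[2])
  data.frame(x_um = runif(n, b[1], b[2]), y_um = runif(n, b[3], b[4]))
}

#' Compare second-wave distances against the random-dot null
#'
#' Computes the signed nearest-neighbour distance of every second-wave
#' point and of an equal number of random dots to the nearest first-wave
#' surface, and summarizes the two distributions (median, quartiles, per
#' replicate when given) together with their median difference and a
#' two-sample Kolmogorov-Smirnov comparison.
#'
#' @param wave1,wave2 point tables (`x_um`, `y_um`; optional `replicate`).
#' @param field field size/bounds for the null (see [random_dot_null()]).
#' @param seed seed for the null draw.
#' @param target_radius_um first-wave surface radius (default 7.5,
#'   approximately a neutrophil radius).
#' @return list with `distances` (data.frame `distance_um`, `set`,
#'   `replicate`), `summary` (per set and replicate: median, q25, q75, n),
#'   `median_difference` (wave2 median minus random median) and `ks_p`.
#' @export
wave_comparison <- function(wave1, wave2, field, seed = NULL,
                            target_radius_um = 7.5) {
  stopifnot(nrow(wave1) > 0, nrow(wave2) > 0)
  d2 <- signed_nn_distance(wave2, wave1, target_radius_um)
  rnd <- random_dot_null(nrow(as.data.frame(wave2)), field, seed)
  dr <- signed_nn_distance(rnd, wave1, target_radius_um)
  rep2 <- if ("replicate" %in% names(as.data.frame(wave2))) {
    as.data.frame(wave2)$replicate
  } else rep(1L, length(d2))
  distances <- rbind(
    data.frame(distance_um = d2, set = "wave2", replicate = rep2),
    data.frame(distance_um = dr, set = "random", replicate = rep2)
  )
  summ <- do.call(rbind, lapply(split(distances, list(distances$set, distances$replicate)),
    function(d) data.frame(set = d$set[1], replicate = d$replicate[1],
                           median = stats::median(d$distance_um),
                           q25 = unname(stats::quantile(d$distance_um, 0.25)),
                           q75 = unname(stats::quantile(d$distance_um, 0.75)),
                           n = nrow(d))))
  rownames(summ) <- NULL
  ks <- suppressWarnings(stats::ks.test(d2, dr))
  list(distances = distances, summary = summ,
       median_difference = stats::median(d2) - stats::median(dr),
       ks_p = ks$p.value)
}

#' Adhesion counts, second/first ratio and diapedesis efficacy
#'
#' Consumes annotated neutrophil positions (wave membership and
#' adherent/transmigrated state are upstream annotations) and reports per
#' wave the adhered count (adherent + transmigrated: every transmigrated
#' cell adhered first), the wave2/wave1 adhesion ratio, and the diapedesis
#' efficacy, transmigrated / (adherent + transmigrated).
#'
#' @param points data.frame with `wave` (1/2) and
#'   `state` (`"adherent"`, `"transmigrated"`, `"unknown"`).
#' @return list with `per_wave` (data.frame `wave`, `n_adherent`,
#'   `n_transmigrated`, `n_total`, `efficacy`) and `adhesion_ratio`
#'   (wave2 total / wave1 total, NA if wave 1 absent).
#' @export
adhesion_metrics <- function(points) {
  stopifnot(all(c("wave", "state") %in% names(points)))
  waves <- sort(unique(points$wave))
  per <- do.call(rbind, lapply(waves, function(w) {
    p <- points[points$wave == w, ]
    na <- sum(p$state == "adherent")
    nt <- sum(p$state == "transmigrated")
    data.frame(wave = w, n_adherent = na, n_transmigrated = nt,
               n_total = na + nt,
               efficacy = if (na + nt > 0) nt / (na + nt) else 0)
  }))
  n1 <- per$n_total[per$wave == 1]
  n2 <- per$n_total[per$wave == 2]
  ratio <- if (length(n1) == 1 && length(n2) == 1 && n1 > 0) n2 / n1 else NA_real_
  list(per_wave = per, adhesion_ratio = ratio)
}

#' Crawling-track statistics
#'
#' Path length (sum of segment lengths), duration and mean speed per
#' track. Tracks with fewer than two points carry no crawling information
#' and are excluded; their count is recorded in the `"excluded"` attribute.
#'
#' @param tracks data.frame with `track_id`, `x`, `y`, and either `t_s`
#'   or `frame`.
#' @param pixel_size_um multiply `x`/`y` by this to get micrometres
#'   (default 1: coordinates already in um).
#' @param frame_interval_s needed when time is given as `frame`.
#' @param replicate optional per-row replicate id for median export.
#' @return data.frame per track: `track_id`, `length_um`, `duration_s`,
#'   `speed_um_s` (and `replicate` if given); attribute `excluded`.
#' @export
track_statistics <- function(tracks, pixel_size_um = 1,
                             frame_interval_s = NULL, replicate = NULL) {
  stopifnot(all(c("track_id", "x", "y") %in% names(tracks)))
  if (!"t_s" %in% names(tracks)) {
    if (!"frame" %in% names(tracks) || is.null(frame_interval_s)) {
      stop("tracks need t_s, or frame plus frame_interval_s")
    }
    tracks$t_s <- tracks$frame * frame_interval_s
  }
  if (!is.null(replicate)) tracks$.rep <- replicate
  sp <- split(tracks, tracks$track_id)
  short <- vapply(sp, nrow, integer(1)) < 2
  out <- do.call(rbind, lapply(sp[!short], function(d) {
    d <- d[order(d$t_s), ]
    seg <- sqrt(diff(d$x)^2 + diff(d$y)^2) * pixel_size_um
    dur <- d$t_s[nrow(d)] - d$t_s[1]
    if (dur <= 0) stop("track duration must be > 0")
    res <- data.frame(track_id = d$track_id[1], length_um = sum(seg),
                      duration_s = dur, speed_um_s = sum(seg) / dur)
    if (".rep" %in% names(d)) res$replicate <- d$.rep[1]
    res
  }))
  if (is.null(out)) out <- data.frame(track_id = integer(0), length_um = numeric(0),
                                      duration_s = numeric(0), speed_um_s = numeric(0))
  rownames(out) <- NULL
  structure(out, excluded = sum(short))
}
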