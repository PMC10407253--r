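#' Baseline-normalize C/N traces to relative kinase activity
#'
#' Subtracts from every cell's trace the mean of its frames before the
#' stimulus, turning C/N ratios into a relative kinase activity parameter
#' centred at zero during baseline. Cells without a single non-missing
#' baseline frame (e.g. first detected after the stimulus) are dropped;
#' their count is recorded in the `"dropped"` attribute.
#'
#' @param traces cells x frames numeric matrix of C/N ratios; columns are
#'   0-based frames `0 .. T-1`, `NA` for missing.
#' @param stimulus_frame 0-based stimulus frame; frames `< stimulus_frame`
#'   are baseline. Must be >= 1.
#' @return matrix of the same shape (minus dropped rows) of relative
#'   activity, with attributes `stimulus_frame` and `dropped`.
#' @export
normalize_baseline <- function(traces, stimulus_frame) {
  traces <- as.matrix(traces)
  if (stimulus_frame < 1) stop("stimulus_frame must be >= 1: no baseline frames")
  if (stimulus_frame > ncol(traces)) stop("stimulus_frame beyond trace length")
  base <- traces[, seq_len(stimulus_frame), drop = FALSE]
  n_base <- rowSums(!is.na(base))
  keep <- n_base >= 1
  dropped <- sum(!keep)
  traces <- traces[keep, , drop = FALSE]
  mu <- rowMeans(base[keep, , drop = FALSE], na.rm = TRUE)
  out <- traces - mu
  attr(out, "stimulus_frame") <- as.integer(stimulus_frame)
  attr(out, "dropped") <- dropped
  out
}

#' Average consecutive frame pairs
#'
#' Smooths an activity matrix by averaging columns in non-overlapping pairs.
#' A trailing odd column is dropped. Pairs are averaged missing-aware: a
#' pair with one missing value keeps the other; an all-missing pair stays
#' missing.
#'
#' @param matrix_ cells x frames numeric matrix.
#' @return cells x `floor(T/2)` matrix.
#' @export
bin_pairs <- function(matrix_) {
  m <- as.matrix(matrix_)
  nb <- floor(ncol(m) / 2)
  if (nb < 1) stop("need at least 2 columns to bin in pairs")
  out <- vapply(seq_len(nb), function(j) {
    rowMeans(m[, c(2L * j - 1L, 2L * j), drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(m)
  out
}

#' Classify cells into activated vs non-activated by hierarchical clustering
#'
#' Post-stimulus activity frames are binned in pairs, remaining missing
#' values imputed by within-row linear interpolation, and cells clustered by
#' agglomerative clustering with Manhattan (L1) distance and Ward.D2
#' linkage, cut at two clusters. The cluster with the higher mean
#' post-stimulus activity is labelled `activated`. Control and treated cells
#' are meant to be clustered jointly; per-condition responder fractions are
#' reported when `condition` is given.
#'
#' If all cells are numerically identical no data-driven split exists; all
#' cells are returned non-activated with a warning rather than an arbitrary
#' partition.
#'
#' @param matrix_ cells x frames relative-activity matrix
#'   (from [normalize_baseline()]), columns = 0-based frames.
#' @param stimulus_frame 0-based stimulus frame; frames `>= stimulus_frame`
#'   enter the clustering.
#' @param condition optional per-cell condition labels (e.g. `"control"`,
#'   `"neutrophil"`) for the fraction report.
#' @param bin average post-stimulus frames in pairs first (default TRUE).
#' @return list with `labels` (factor `activated` / `non-activated` per
#'   cell), `fractions` (named numeric, per condition, if `condition`
#'   given), `hclust` (the dendrogram, NULL in the degenerate case) and
#'   `binned` (the matrix that was clustered).
#' @export
cluster_responders <- function(matrix_, stimulus_frame, condition = NULL,
                               bin = TRUE) {
  m <- as.matrix(matrix_)
  if (nrow(m) < 2) stop("need at least 2 cells to cluster")
  if (!is.null(condition)) stopifnot(length(condition) == nrow(m))
  post <- m[, (stimulus_frame + 1L):ncol(m), drop = FALSE]
  if (bin) post <- bin_pairs(post)
  post <- t(apply(post, 1, impute_row))
  if (any(is.na(post))) stop("cells with no post-stimulus data cannot be clustered")

  lev <- c("non-activated", "activated")
  if (max(post) - min(post) < .Machine$double.eps^0.5) {
    warning("all cells identical: returning all cells non-activated")
    labels <- factor(rep("non-activated", nrow(m)), levels = lev)
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::dist(post, method = "manhattan"),
                        method = "ward.D2")
    k2 <- stats::cutree(hc, k = 2)
    means <- tapply(rowMeans(post), k2, mean)
    act <- as.integer(names(means)[which.max(means)])
    labels <- factor(ifelse(k2 == act, "activated", "non-activated"),
                     levels = lev)
  }
  fractions <- NULL
  if (!is.null(condition)) {
    f <- tapply(labels == "activated", condition, mean)
    fractions <- stats::setNames(as.numeric(f), names(f))
  }
  list(labels = labels, fractions = fractions, hclust = hc, binned = post)
}

impute_row <- function(x) {
  if (!anyNA(x) || all(is.na(x))) return(x)
  idx <- seq_along(x)
  stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
}

#' Per-frame mean and 95% confidence interval by condition
#'
#' Summarizes an activity matrix the way the time-series figures do: per
#' frame and condition, the mean over non-missing cells with a normal
#' approximation 95% CI (mean +/- 1.96 SEM).
#'
#' @param matrix_ cells x frames matrix, columns = 0-based frames.
#' @param condition per-cell condition labels.
#' @param frame_interval_s optional seconds per frame, adds a `time_s`
#'   column.
#' @return data.frame with `frame`, `condition`, `mean`, `lo`, `hi`, `n`.
#' @export
summarize_timeseries <- function(matrix_, condition,
                                 frame_interval_s = NULL) {
  m <- as.matrix(matrix_)
  stopifnot(length(condition) == nrow(m))
  if (min(table(condition)) < 2) stop("need >= 2 cells per condition")
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), condition), function(rows) {
    sub <- m[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    sem <- apply(sub, 2, stats::sd, na.rm = TRUE) / sqrt(n)
    data.frame(frame = seq_len(ncol(m)) - 1L,
               condition = condition[rows[1]],
               mean = mu, lo = mu - 1.96 * sem, hi = mu + 1.96 * sem, n = n)
  }))
  if (!is.null(frame_interval_s)) out$time_s <- out$frame * frame_interval_s
  rownames(out) <- NULL
  out
}
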