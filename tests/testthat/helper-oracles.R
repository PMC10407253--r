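# Independent reference implementations used as oracles. These deliberately
# use naive algorithms and share no code with the package internals.

# Brute-force agglomerative Ward.D2 on Manhattan distances: squared
# dissimilarities updated with the Lance-Williams Ward formula, merge height
# = sqrt of the minimal squared dissimilarity. Returns heights in merge
# order and the member set created by each merge.
ward_d2_oracle <- function(x) {
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x, method = "manhattan"))^2
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  heights <- numeric(n - 1)
  merged_sets <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    idx <- which(alive)
    bv <- Inf; bi <- NA; bj <- NA
    for (a in idx) for (b in idx) {
      if (a < b && D2[a, b] < bv) { bv <- D2[a, b]; bi <- a; bj <- b }
    }
    heights[m] <- sqrt(bv)
    for (k in idx) {
      if (k == bi || k == bj) next
      D2[bi, k] <- D2[k, bi] <-
        ((sizes[bi] + sizes[k]) * D2[bi, k] +
         (sizes[bj] + sizes[k]) * D2[bj, k] -
         sizes[k] * bv) / (sizes[bi] + sizes[bj] + sizes[k])
    }
    members[[bi]] <- sort(c(members[[bi]], members[[bj]]))
    sizes[bi] <- sizes[bi] + sizes[bj]
    alive[bj] <- FALSE
    merged_sets[[m]] <- members[[bi]]
  }
  list(heights = heights, merged_sets = merged_sets)
}

# Member set created at each merge of an hclust tree.
hclust_merged_sets <- function(hc) {
  n <- nrow(hc$merge) + 1
  merged <- vector("list", n - 1)
  expand <- function(v) if (v < 0) -v else merged[[v]]
  for (m in seq_len(n - 1)) {
    merged[[m]] <- sort(c(expand(hc$merge[m, 1]), expand(hc$merge[m, 2])))
  }
  merged
}

# Naive grayscale opening (erosion then dilation) with a disc of the given
# radius; O(n^2 * r^2), only for tiny images.
naive_opening <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  apply_se <- function(x, fun, pad) {
    out <- matrix(0, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      rr <- r + offs$dr; cc <- c + offs$dc
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      vals <- x[cbind(rr[ok], cc[ok])]
      if (any(!ok)) vals <- c(vals, pad)
      out[r, c] <- fun(vals)
    }
    out
  }
  # pad with +Inf for erosion / -Inf for dilation == ignore outside pixels
  er <- apply_se(img, min, Inf)
  apply_se(er, max, -Inf)
}

# Brute-force nearest-nucleus pixel assignment: every pixel of the allowed
# region goes to the nucleus with the closest pixel (Euclidean).
naive_nearest_nucleus <- function(nuclei, allowed) {
  ids <- sort(unique(nuclei[nuclei > 0]))
  px <- lapply(ids, function(i) which(nuclei == i, arr.ind = TRUE))
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  tgt <- which(allowed, arr.ind = TRUE)
  for (k in seq_len(nrow(tgt))) {
    d <- vapply(px, function(p) {
      min((p[, 1] - tgt[k, 1])^2 + (p[, 2] - tgt[k, 2])^2)
    }, numeric(1))
    out[tgt[k, 1], tgt[k, 2]] <- ids[which.min(d)]
  }
  out
}

# Disk mask used to reconstruct ground-truth compartments from the
# generator's placement table, independent of package internals.
truth_disk <- function(h, w, cr, cc, diameter) {
  m <- matrix(FALSE, h, w)
  m[(row(m) - cr)^2 + (col(m) - cc)^2 <= (diameter / 2)^2] <- TRUE
  m
}

# Joint control + neutrophil responder-fraction run used by several tests.
joint_fraction_run <- function(seed, n = 200, noise_sd = 0.05) {
  ctrl <- gen_traces(n, ktr_preset("control", noise_sd = noise_sd), seed = seed)
  neut <- gen_traces(n, ktr_preset("neutrophil", noise_sd = noise_sd),
                     seed = seed + 10000L)
  m <- rbind(ctrl$cn, neut$cn)
  act <- normalize_baseline(m, 5)
  cl <- cluster_responders(act, 5,
                           condition = rep(c("control", "neutrophil"), each = n))
  list(fractions = cl$fractions, labels = cl$labels,
       truth = c(ctrl$truth$responder, neut$truth$responder))
}
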