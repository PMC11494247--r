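# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately re-derive each quantity by the most naive route
# (double loops, enumeration, direct formulas) and never call the package
# code paths they check.

# --- naive GLCM oracle -------------------------------------------------
# Enumerate every ordered voxel pair inside the window at the 13 unit
# offsets, both directions, both endpoints in the mask.
oracle_offsets <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
  c(1, 1, 1), c(-1, 1, 1), c(1, -1, 1), c(-1, -1, 1))

oracle_glcm <- function(bins, mask, center, radius, n_bins = 8) {
  dims <- dim(bins)
  lo <- pmax(center - radius, 1)
  hi <- pmin(center + radius, dims)
  counts <- matrix(0, n_bins, n_bins)
  for (x in lo[1]:hi[1]) for (y in lo[2]:hi[2]) for (z in lo[3]:hi[3]) {
    if (!mask[x, y, z]) next
    for (o in seq_len(nrow(oracle_offsets))) {
      q <- c(x, y, z) + oracle_offsets[o, ]
      if (any(q < lo) || any(q > hi)) next
      if (!mask[q[1], q[2], q[3]]) next
      a <- bins[x, y, z] + 1L
      b <- bins[q[1], q[2], q[3]] + 1L
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

oracle_haralick <- function(p) {
  e <- s <- ct <- h <- 0
  n <- nrow(p)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    q <- p[i, j]
    e <- e + q * q
    if (q > 0) s <- s - q * log(q)
    ct <- ct + (i - j)^2 * q
    h <- h + q / (1 + abs(i - j))
  }
  c(Energy = e, Entropy = s, Contrast = ct, Homogeneity = h)
}

# --- direct-formula statistic oracles ----------------------------------
oracle_stat <- function(x, stat, mode_res = 1) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  s <- if (n >= 2) sqrt(sum((x - m)^2) / (n - 1)) else NA_real_
  switch(stat,
    Mean = m,
    SD = s,
    Median = {
      xs <- sort(x)
      if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    },
    QD = {
      q <- function(pr) {  # type-7 linear interpolation
        h <- (n - 1) * pr + 1
        lo <- floor(h)
        xs <- sort(x)
        xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
      }
      (q(0.75) - q(0.25)) / 2
    },
    Mode = {
      b <- floor(x / mode_res + 1e-9)
      tb <- table(b)
      (min(as.numeric(names(tb)[tb == max(tb)])) + 0.5) * mode_res
    },
    Variance = if (n >= 2) s^2 else NA_real_,
    Range = max(x) - min(x),
    SM = if (n >= 2) s / sqrt(n) else NA_real_,
    USS = sum(x^2),
    CSS = sum((x - m)^2),
    CV = if (n < 2 || m == 0) NA_real_ else s / m,
    Skewness = if (n < 3 || m2 == 0) NA_real_ else
      (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2),
    Kurtosis = if (n < 4 || m2 == 0) NA_real_ else
      ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3)))
}

# --- concordant-pair AUC oracle ----------------------------------------
oracle_auc <- function(pred, labels) {
  pos <- pred[labels == 1]
  neg <- pred[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# --- brute-force SUVpeak oracle ----------------------------------------
oracle_suv_peak <- function(vals, mask, spacing, vol_cm3 = 1) {
  r <- (3 * vol_cm3 * 1000 / (4 * pi))^(1 / 3)
  dims <- dim(vals)
  centers <- which(mask, arr.ind = TRUE)
  best <- -Inf
  for (i in seq_len(nrow(centers))) {
    cen <- centers[i, ]
    acc <- 0; cnt <- 0
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      d <- sqrt(sum(((c(x, y, z) - cen) * spacing)^2))
      if (d <= r + 1e-9) { acc <- acc + vals[x, y, z]; cnt <- cnt + 1 }
    }
    best <- max(best, acc / cnt)
  }
  best
}

# --- fixture builders ---------------------------------------------------
# ellipsoid mask centred in a grid, semi-axes in mm
make_ellipsoid_mask <- function(dims, spacing, semi_mm,
                                center_mm = (dims - 1) * spacing / 2) {
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  q <- outer(((xs - center_mm[1]) / semi_mm[1])^2,
             ((ys - center_mm[2]) / semi_mm[2])^2, `+`)
  q <- outer(q, ((zs - center_mm[3]) / semi_mm[3])^2, `+`)
  q <= 1
}

# a box mask spanning a given number of voxels per axis, placed at offset
make_box_mask <- function(dims, n_vox, offset = c(1, 1, 1)) {
  m <- array(FALSE, dims)
  m[offset[1]:(offset[1] + n_vox[1] - 1),
    offset[2]:(offset[2] + n_vox[2] - 1),
    offset[3]:(offset[3] + n_vox[3] - 1)] <- TRUE
  m
}

# small, fast phantom settings for pipeline-level tests
fast_phantom_config <- function(...) {
  phantom_config(...)
}
fast_texture_args <- list(K_range = 1:4, n_init = 2)

# hand-built subregion model for indicator unit tests
make_model <- function(sites, clusters, n, means, K = max(clusters),
                       site_profiles = NULL) {
  if (is.null(site_profiles)) {
    site_profiles <- matrix(0, length(unique(sites)), K,
                            dimnames = list(sort(unique(sites)), NULL))
    for (i in seq_along(sites))
      site_profiles[as.character(sites[i]), clusters[i]] <-
        site_profiles[as.character(sites[i]), clusters[i]] + n[i]
  }
  structure(list(K = K,
                 subregions = data.frame(site = as.character(sites),
                                         cluster = clusters, n = n),
                 means = means, M = length(sites),
                 site_profiles = site_profiles),
            class = "subregion_model")
}
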