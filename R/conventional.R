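# Conventional per-lesion features and the 13 patient-level statistics that
# turn them into 104 spatial-heterogeneity indicators (13 statistics x 8
# features).

# Feature short names used in indicator columns, in fixed order:
#   HU   mean CT value over the VOI (HU)
#   Min  minor axis length (mm)      Maj  major axis length (mm)
#   Vol  voxel ("pixel") count       TLG  total lesion glycolysis (SUV*cm^3)
#   Mean SUVmean   Peak SUVpeak      Max  SUVmax
conv_features <- c("HU", "Min", "Maj", "Vol", "TLG", "Mean", "Peak", "Max")

conv_stats <- c("Mean", "SD", "Median", "QD", "Mode", "Variance", "Range",
                "SM", "USS", "CSS", "CV", "Kurtosis", "Skewness")

# Binning resolution used by the (binned) mode, per feature: 1 HU for CT
# values, 0.1 mm for axis lengths, 1 for voxel counts, 0.01 for SUV-derived
# quantities.
conv_mode_resolution <- c(HU = 1, Min = 0.1, Maj = 0.1, Vol = 1, TLG = 0.01,
                          Mean = 0.01, Peak = 0.01, Max = 0.01)

#' Principal axis lengths of a voxel mask
#'
#' Eigen-decomposition of the population covariance of the mask voxels'
#' physical coordinates; axis length = 4*sqrt(eigenvalue) (the IBSI major /
#' minor axis convention). Major is the largest, minor the second-largest
#' of the three 3-D eigenvalues.
#'
#' @param mask Logical 3-D array with at least 2 `TRUE` voxels.
#' @param spacing_mm Voxel spacing (mm).
#' @return Named numeric `c(major_mm, minor_mm)`; a `degenerate` attribute is
#'   set when the mask is (near) collinear and the minor axis ~ 0.
#' @export
axis_lengths <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) stopf("axis_lengths needs at least 2 voxels")
  xyz <- sweep(idx, 2, spacing_mm, `*`)
  cen <- colMeans(xyz)
  xc <- sweep(xyz, 2, cen)
  covm <- crossprod(xc) / nrow(xc)           # population covariance
  ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  out <- c(major_mm = 4 * sqrt(ev[1]), minor_mm = 4 * sqrt(ev[2]))
  if (ev[2] < 1e-12 * max(ev[1], 1)) attr(out, "degenerate") <- TRUE
  out
}

#' SUVpeak by exhaustive sphere placement
#'
#' Maximum over candidate centres (every voxel of the mask) of the mean SUV
#' inside a sphere of `sphere_volume_cm3` centred there. The sphere includes
#' all image-grid voxels whose centres fall within the radius (PERCIST-style,
#' 1 cm^3 by default); when the mask is smaller than the sphere the mean is
#' taken over the available in-grid, in-sphere voxels.
#'
#' @param pet PET [image_volume()] or numeric 3-D array.
#' @param mask Logical array, non-empty.
#' @param spacing_mm Voxel spacing (mm); defaults to the volume's.
#' @param sphere_volume_cm3 Sphere volume (default 1).
#' @return SUVpeak (scalar).
#' @export
suv_peak <- function(pet, mask, spacing_mm = NULL, sphere_volume_cm3 = 1.0) {
  vals <- if (inherits(pet, "image_volume")) pet$values else pet
  spacing_mm <- spacing_mm %||% pet$spacing_mm
  if (!any(mask)) stopf("suv_peak: empty mask")
  r_mm <- (3 * sphere_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  rv <- floor(r_mm / spacing_mm)
  offs <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2],
                                dz = -rv[3]:rv[3]))
  keep <- sqrt(colSums((t(offs) * spacing_mm)^2)) <= r_mm + 1e-9
  offs <- offs[keep, , drop = FALSE]
  dims <- dim(vals)
  centers <- which(mask, arr.ind = TRUE)
  sums <- numeric(nrow(centers))
  cnts <- numeric(nrow(centers))
  for (o in seq_len(nrow(offs))) {
    p <- sweep(centers, 2, offs[o, ], `+`)
    ok <- p[, 1] >= 1 & p[, 1] <= dims[1] & p[, 2] >= 1 & p[, 2] <= dims[2] &
      p[, 3] >= 1 & p[, 3] <= dims[3]
    lin <- p[ok, 1] + dims[1] * (p[ok, 2] - 1) + dims[1] * dims[2] * (p[ok, 3] - 1)
    sums[ok] <- sums[ok] + vals[lin]
    cnts[ok] <- cnts[ok] + 1
  }
  max(sums / cnts)
}

#' Eight conventional features of one lesion VOI
#'
#' CT features: mean CT value (HU), minor/major axis length (mm), voxel
#' count. PET features: TLG = SUVmean x volume (cm^3), SUVmean, SUVpeak,
#' SUVmax.
#'
#' @param ct,pet [image_volume()]s sharing the VOI's frame.
#' @param mask Logical 3-D array (non-empty).
#' @param spacing_mm Voxel spacing; defaults to the CT volume's.
#' @return One-row data.frame with columns `ct_value, minor_axis_mm,
#'   major_axis_mm, pixel_number, tlg, suv_mean, suv_peak, suv_max`.
#' @export
lesion_features <- function(ct, pet, mask, spacing_mm = NULL) {
  spacing_mm <- spacing_mm %||% ct$spacing_mm
  ctv <- if (inherits(ct, "image_volume")) ct$values else ct
  petv <- if (inherits(pet, "image_volume")) pet$values else pet
  n <- sum(mask)
  if (n < 1L) stopf("lesion_features: empty mask")
  ax <- if (n >= 2L) axis_lengths(mask, spacing_mm) else
    c(major_mm = NA_real_, minor_mm = NA_real_)
  vol_cm3 <- n * prod(spacing_mm) / 1000
  suv <- petv[mask]
  suv_mean <- mean(suv)
  data.frame(ct_value = mean(ctv[mask]),
             minor_axis_mm = unname(ax["minor_mm"]),
             major_axis_mm = unname(ax["major_mm"]),
             pixel_number = n,
             tlg = suv_mean * vol_cm3,
             suv_mean = suv_mean,
             suv_peak = suv_peak(petv, mask, spacing_mm),
             suv_max = max(suv))
}

# Binned mode: discretize to fixed-width bins, return the midpoint of the
# most frequent bin; the lowest bin wins ties.
binned_mode <- function(x, resolution) {
  b <- floor(x / resolution + 1e-9)
  tab <- table(b)
  best <- min(as.numeric(names(tab)[tab == max(tab)]))
  (best + 0.5) * resolution
}

#' One of the 13 patient-level statistics
#'
#' Applied to the per-lesion values of one conventional feature. Pinned
#' definitions: `SD`/`Variance`/`CSS` are sample (n-1 / centered) forms;
#' `QD` = (Q3-Q1)/2 with linear-interpolation quantiles; `Mode` is the
#' binned mode (see `mode_resolution`); `SM` = SD/sqrt(n) (standard error of
#' the mean); `USS` = sum(x^2); `CV` = SD/mean; `Kurtosis` is bias-corrected
#' excess kurtosis (needs n >= 4); `Skewness` is the adjusted Fisher-Pearson
#' coefficient (needs n >= 3). Statistics undefined at the available n (or
#' CV at mean 0, or shape statistics of a constant vector) are returned as
#' `NA`, never imputed.
#'
#' @param values Finite numeric vector (one entry per lesion), length >= 1.
#' @param stat One of `r paste(conv_stats, collapse=", ")`.
#' @param mode_resolution Bin width for `Mode` (default 1).
#' @return Scalar value or `NA`.
#' @export
patient_statistic <- function(values, stat = conv_stats, mode_resolution = 1) {
  stat <- match.arg(stat)
  if (length(values) < 1L || any(!is.finite(values)))
    stopf("patient_statistic: values must be finite and non-empty")
  n <- length(values)
  m <- mean(values)
  switch(stat,
    Mean = m,
    Median = median(values),
    QD = unname(diff(quantile(values, c(0.25, 0.75), type = 7)) / 2),
    Mode = binned_mode(values, mode_resolution),
    Range = max(values) - min(values),
    USS = sum(values^2),
    CSS = sum((values - m)^2),
    SD = if (n >= 2) sd(values) else NA_real_,
    Variance = if (n >= 2) var(values) else NA_real_,
    SM = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
    CV = {
      if (n < 2) NA_real_
      else if (m == 0) NA_real_
      else sd(values) / m
    },
    Skewness = {
      m2 <- mean((values - m)^2)
      if (n < 3 || m2 == 0) NA_real_
      else (mean((values - m)^3) / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
    },
    Kurtosis = {
      m2 <- mean((values - m)^2)
      if (n < 4 || m2 == 0) NA_real_
      else {
        g2 <- mean((values - m)^4) / m2^2 - 3
        ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
      }
    })
}

# Map a per-lesion feature table (one row per VOI, lesion_features() columns)
# to the named 8-feature matrix used by the indicator block.
lesion_feature_matrix <- function(feat_df) {
  cbind(HU = feat_df$ct_value, Min = feat_df$minor_axis_mm,
        Maj = feat_df$major_axis_mm, Vol = feat_df$pixel_number,
        TLG = feat_df$tlg, Mean = feat_df$suv_mean,
        Peak = feat_df$suv_peak, Max = feat_df$suv_max)
}

#' The 104-indicator conventional block for one patient
#'
#' Applies the 13 statistics to each of the 8 conventional features of the
#' patient's lesions. Column names follow `<feature>_<statistic>` (e.g.
#' `Max_SM` = standard error of the mean of SUVmax, `HU_Kurtosis`).
#'
#' @param feat_df Per-lesion feature table from [lesion_features()] (one row
#'   per surviving VOI).
#' @return Named numeric vector of length 104 (NAs preserved).
#' @export
conventional_block <- function(feat_df) {
  fm <- lesion_feature_matrix(feat_df)
  out <- numeric(0)
  for (f in conv_features) {
    vals <- fm[, f]
    ok <- is.finite(vals)
    for (s in conv_stats) {
      v <- if (any(ok)) patient_statistic(vals[ok], s,
                                          conv_mode_resolution[[f]]) else
        NA_real_
      out[paste(f, s, sep = "_")] <- v
    }
  }
  out
}

#' Conventional indicator table for a cohort
#'
#' @param lesion_table data.frame with a `patient_id` column plus the
#'   [lesion_features()] columns, one row per VOI.
#' @return data.frame: one row per patient (patients with no VOI are dropped
#'   with a message), `patient_id` plus the 104 indicator columns.
#' @export
conventional_indicator_table <- function(lesion_table) {
  ids <- unique(lesion_table$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- lesion_table[lesion_table$patient_id == id, , drop = FALSE]
    if (nrow(sub) < 1L) return(NULL)
    as.data.frame(c(list(patient_id = id), as.list(conventional_block(sub))))
  })
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop))
    message(sprintf("excluding %d patient(s) with no surviving VOI",
                    sum(drop)))
  do.call(rbind, rows[!drop])
}
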