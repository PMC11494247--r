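# Voxel-level Haralick texture maps on CT: min-max rescale to 256 gray
# levels, discretize with bin width 32 (8 bins), per-voxel GLCM over a cubic
# window with the 13 unique unit 3-D offsets, and the four features Energy,
# Entropy, Contrast, Homogeneity.

#' Min-max rescale in-mask CT intensities to 256 gray levels
#'
#' @param ct [image_volume()] or numeric 3-D array.
#' @param mask Logical array of the VOI.
#' @return Integer array (same shape) with in-mask values 0..255 and NA
#'   outside the mask; attribute `degenerate` is TRUE for a constant VOI
#'   (mapped to level 0).
#' @export
rescale_gray <- function(ct, mask) {
  vals <- if (inherits(ct, "image_volume")) ct$values else ct
  out <- array(NA_integer_, dim = dim(vals))
  x <- vals[mask]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out[mask] <- 0L
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  lev <- as.integer(round((x - rng[1]) / (rng[2] - rng[1]) * 255))
  out[mask] <- lev
  attr(out, "degenerate") <- FALSE
  out
}

#' Discretize 256 gray levels into bins of width 32
#'
#' @param levels Integer array/vector with values 0..255 (NA passed through).
#' @param bin_width Bin width (default 32, giving 8 bins 0..7).
#' @return Same shape, bin indices `floor(level / bin_width)`.
#' @export
discretize <- function(levels, bin_width = 32) {
  if (any(levels < 0 | levels > 255, na.rm = TRUE))
    stopf("discretize: levels must lie in 0..255")
  out <- levels
  out[] <- as.integer(floor(levels / bin_width))
  out
}

#' Normalized GLCM of the window centred at one voxel
#'
#' Symmetric co-occurrence over the 13 unique unit 3-D offsets (both
#' directions counted) between voxel pairs that both lie inside the cubic
#' window, the grid and the mask; normalized to sum 1. A window with zero
#' valid pairs returns an all-zero matrix with attribute `degenerate`.
#'
#' @param bins Integer array of gray bins (NA outside mask is fine).
#' @param mask Logical array.
#' @param center Integer length-3 voxel index (1-based) inside the mask.
#' @param window_radius Cube radius in voxels (default 2, a 5^3 window).
#' @param n_bins Number of gray bins (default 8).
#' @return `n_bins` x `n_bins` numeric matrix.
#' @export
voxel_glcm <- function(bins, mask, center, window_radius = 2, n_bins = 8) {
  if (!mask[center[1], center[2], center[3]])
    stopf("voxel_glcm: center voxel is not in the mask")
  b <- bins
  b[is.na(b)] <- 0L
  p <- cpp_voxel_glcm(as.integer(b), as.logical(mask), dim(mask),
                      as.integer(center), as.integer(window_radius),
                      as.integer(n_bins))
  if (sum(p) == 0) attr(p, "degenerate") <- TRUE
  p
}

#' Haralick features of a normalized GLCM
#'
#' Energy = sum p^2; Entropy = -sum p log p (natural log, 0 log 0 = 0);
#' Contrast = sum (i-j)^2 p; Homogeneity = sum p / (1 + |i-j|).
#'
#' @param glcm Square matrix summing to 1.
#' @return Named numeric vector of the 4 features.
#' @export
haralick <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-8)
    stopf("haralick: GLCM must be normalized (sum 1)")
  n <- nrow(glcm)
  i <- row(glcm); j <- col(glcm)
  p <- glcm
  pl <- p[p > 0]
  c(Energy = sum(p^2),
    Entropy = -sum(pl * log(pl)),
    Contrast = sum((i - j)^2 * p),
    Homogeneity = sum(p / (1 + abs(i - j))))
}

#' Voxel-level texture maps for one VOI
#'
#' Runs the full per-voxel chain (rescale, discretize, windowed GLCM,
#' Haralick features) for every voxel of the mask.
#'
#' @inheritParams rescale_gray
#' @param window_radius Cube radius in voxels (default 2).
#' @param bin_width Gray-bin width (default 32).
#' @return List: `features` (n_voxel x 4 matrix, NA rows for degenerate
#'   windows), `degenerate` (logical), `voxel_index` (0-based linear index
#'   into the volume), `provenance` (window size, offsets, gray levels).
#' @export
texture_maps <- function(ct, mask, window_radius = 2, bin_width = 32) {
  lev <- rescale_gray(ct, mask)
  bins <- discretize(lev, bin_width)
  bins[is.na(bins)] <- 0L
  n_bins <- as.integer(ceiling(256 / bin_width))
  res <- cpp_texture_maps(as.integer(bins), as.logical(mask), dim(mask),
                          as.integer(window_radius), n_bins)
  res$provenance <- list(window = 2L * window_radius + 1L, offsets = 13L,
                         gray_levels = 256L, bin_width = bin_width,
                         rescale_degenerate = isTRUE(attr(lev, "degenerate")))
  res
}
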