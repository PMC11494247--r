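# The three texture-cluster spatial-heterogeneity indicators. All are
# diversity indices over the subregion decomposition, chosen to grow with
# genuine between-site texture diversity and to be robust to the Gaussian
# mixture splitting homogeneous texture into several components:
#   cSE     Rao's quadratic entropy over cross-site subregion pairs,
#           computed from the dissimilarity matrix with voxel-share weights;
#   cluDev  generalized Jensen-Shannon divergence of the sites' cluster
#           occupancy profiles (between-site "beta" diversity of habitats);
#   cludiss sample SD of the cross-site entries of the dissimilarity matrix.
# Natural logarithm throughout. Subregion means live on a fixed unit-range
# feature scale (see cluster_subregions), so dissimilarity magnitudes are
# comparable across patients.

#' Subregion dissimilarity matrix
#'
#' Pairwise Euclidean distances between subregion mean texture vectors (on
#' the fixed unit-range feature scale): an M x M symmetric non-negative
#' matrix with zero diagonal.
#'
#' @param model A [cluster_subregions()] fit.
#' @return Numeric M x M matrix.
#' @export
dissimilarity_matrix <- function(model) {
  D <- as.matrix(dist(model$means))
  dimnames(D) <- NULL
  D
}

#' Cluster site entropy (cSE)
#'
#' Rao's quadratic entropy restricted to cross-site subregion pairs:
#' `sum_(i,j: site_i != site_j) pi_i pi_j D_ij / sum pi_i pi_j`, where
#' `pi_i` is subregion i's share of the patient's pooled voxels. It is 0
#' when all subregions share one texture signature (however the mixture
#' splits them) and grows with the textural dissimilarity between lesion
#' sites. Degenerate conventions: fewer than 2 subregions, no cross-site
#' pair, or an all-zero dissimilarity matrix give cSE = 0.
#'
#' @param D Dissimilarity matrix from [dissimilarity_matrix()].
#' @param model The matching [cluster_subregions()] fit (site ids and voxel
#'   weights).
#' @return cSE (scalar >= 0).
#' @export
cluster_site_entropy <- function(D, model) {
  M <- nrow(D)
  if (is.null(M) || M < 2) return(0)
  sub <- model$subregions
  w <- sub$n / sum(sub$n)
  cross <- outer(sub$site, sub$site, `!=`)
  wt <- outer(w, w) * cross
  tot <- sum(wt)
  if (tot == 0 || sum(D) == 0) return(0)
  sum(wt * D) / tot
}

#' Group diversity matrix (GDM)
#'
#' K x K two-dimensional histogram over cross-site subregion pairs: for every
#' pair of subregions from different lesion sites with cluster labels (k, l),
#' cell (k, l) is incremented; the matrix is then symmetrized by adding its
#' transpose off the diagonal. Requires at least 2 sites (spatial
#' heterogeneity is undefined within a single site).
#'
#' @param model A [cluster_subregions()] fit.
#' @return Integer K x K matrix.
#' @export
group_diversity_matrix <- function(model) {
  sub <- model$subregions
  if (length(unique(sub$site)) < 2)
    stopf("single-site patient: spatial heterogeneity undefined")
  K <- model$K
  gdm <- matrix(0L, K, K)
  M <- nrow(sub)
  for (i in seq_len(M - 1)) for (j in seq(i + 1, M)) {
    if (sub$site[i] == sub$site[j]) next
    gdm[sub$cluster[i], sub$cluster[j]] <-
      gdm[sub$cluster[i], sub$cluster[j]] + 1L
  }
  sym <- gdm + t(gdm)
  diag(sym) <- diag(gdm)
  sym
}

#' Cluster diversity (cluDev)
#'
#' Generalized Jensen-Shannon divergence of the lesion sites' cluster
#' occupancy profiles: `H(sum_s w_s p_s) - sum_s w_s H(p_s)`, with `p_s`
#' site s's voxel distribution over texture clusters and `w_s` its voxel
#' share. 0 iff all sites use clusters in identical proportions; equals
#' ln(S) for S equally-sized sites with disjoint cluster usage. Requires
#' >= 2 sites.
#'
#' @param model A [cluster_subregions()] fit.
#' @return cluDev (scalar >= 0).
#' @export
cluster_diversity <- function(model) {
  prof <- model$site_profiles
  if (nrow(prof) < 2)
    stopf("single-site patient: spatial heterogeneity undefined")
  w <- rowSums(prof) / sum(prof)
  p <- prof / rowSums(prof)
  pooled <- colSums(p * w)
  h_site <- apply(p, 1, shannon_entropy)
  shannon_entropy(pooled) - sum(w * h_site)
}

#' Cluster dissimilarity standard deviation (cludiss)
#'
#' Sample standard deviation of the cross-site entries of the dissimilarity
#' matrix; 0 when there are fewer than 2 cross-site pairs.
#'
#' @param model A [cluster_subregions()] fit.
#' @param D Matching [dissimilarity_matrix()].
#' @return cludiss (scalar >= 0).
#' @export
cluster_dissimilarity_sd <- function(model, D) {
  sub <- model$subregions
  M <- nrow(sub)
  if (M < 2) return(0)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  cross <- sub$site[pairs[, 1]] != sub$site[pairs[, 2]]
  d <- D[pairs][cross]
  if (length(d) < 2) return(0)
  sd(d)
}

#' Texture heterogeneity indicators for one patient
#'
#' Runs the full texture chain over all VOIs of one patient: voxel-level
#' Haralick maps per VOI (CT only), pooled GMM subregion clustering,
#' dissimilarity matrix, and the three indicators.
#'
#' @param ct CT [image_volume()].
#' @param vois List of VOIs (>= 2 sites) from [extract_vois()].
#' @param K_range,n_init,seed Passed to [cluster_subregions()].
#' @param window_radius,bin_width Passed to [texture_maps()].
#' @return List: `indicators` (named numeric: cSE, cluDev, cludiss), `model`,
#'   `D`, `gdm`.
#' @export
texture_indicators <- function(ct, vois, K_range = 1:8, n_init = 5, seed = 1,
                               window_radius = 2, bin_width = 32) {
  if (length(vois) < 2)
    stopf("single-site patient: spatial heterogeneity undefined")
  feats <- vector("list", length(vois))
  sites <- vector("list", length(vois))
  for (i in seq_along(vois)) {
    tm <- texture_maps(ct, vois[[i]]$mask, window_radius, bin_width)
    feats[[i]] <- tm$features
    sites[[i]] <- rep(vois[[i]]$lesion_id, nrow(tm$features))
  }
  features <- do.call(rbind, feats)
  sites <- unlist(sites)
  n_bins <- ceiling(256 / bin_width)
  fscale <- c(Energy = 1, Entropy = log(n_bins^2),
              Contrast = (n_bins - 1)^2, Homogeneity = 1)
  model <- cluster_subregions(features, sites, K_range, n_init, seed,
                              feature_scale = fscale)
  D <- dissimilarity_matrix(model)
  gdm <- group_diversity_matrix(model)
  list(indicators = c(cSE = cluster_site_entropy(D, model),
                      cluDev = cluster_diversity(model),
                      cludiss = cluster_dissimilarity_sd(model, D)),
       model = model, D = D, gdm = gdm)
}
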