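# Gaussian-mixture subregion clustering of pooled voxel texture vectors.

# Fit a full-covariance GMM for one K with several seeded initializations
# (kmeans starts refined by EM); returns the best fit by log-likelihood.
fit_gmm <- function(X, K, n_init = 5, seed = 1, max_iter = 200, tol = 1e-8,
                    reg = 1e-6) {
  n <- nrow(X)
  if (K > n) stopf("clustering infeasible: K = %d exceeds %d voxels", K, n)
  best <- NULL
  for (init in seq_len(n_init)) {
    means0 <- with_seed(derive_seed(seed, 1000L * K + init), {
      if (K == 1L) matrix(colMeans(X), nrow = 1)
      else {
        km <- tryCatch(
          suppressWarnings(kmeans(X, centers = K, nstart = 1, iter.max = 30)),
          error = function(e) NULL)
        if (is.null(km)) X[sample.int(n, K), , drop = FALSE] else km$centers
      }
    })
    fit <- cpp_gmm_em(X, means0, max_iter, tol, reg)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  d <- ncol(X)
  n_par <- (K - 1) + K * d + K * d * (d + 1) / 2
  best$bic <- -2 * best$loglik + n_par * log(n)
  best$K <- K
  best
}

#' Cluster pooled voxel texture vectors into subregions
#'
#' Pools the texture 4-vectors of all VOIs of one patient, z-score
#' standardizes each feature, fits Gaussian mixtures for each K in `K_range`
#' (full covariance, `n_init` seeded initializations each), selects K by BIC,
#' and labels voxels by maximum posterior responsibility. A subregion is the
#' set of voxels of one lesion site carrying one cluster label; empty
#' (site, cluster) combinations are omitted.
#'
#' @param features Matrix n_voxel x 4 of Haralick vectors (rows with NA are
#'   dropped as degenerate).
#' @param sites Integer/character vector of lesion site ids per voxel row.
#' @param K_range Candidate cluster counts (default 1:8).
#' @param n_init Seeded initializations per K (default 5).
#' @param seed RNG seed.
#' @param feature_scale Fixed divisors mapping each feature to a comparable
#'   unit range before distance computation; the default uses the features'
#'   theoretical bounds for 8 gray bins (Energy and Homogeneity already in
#'   (0,1]; Entropy bounded by ln 64; Contrast by (8-1)^2). GMM fitting
#'   itself uses per-patient z-scores; distances deliberately do not, so
#'   dissimilarity magnitudes remain comparable across patients.
#' @return `subregion_model`: list with `K`, `labels` (per retained voxel),
#'   `sites`, `bic` (per K), `subregions` (data.frame site/cluster/n),
#'   `means` (M x 4 matrix of subregion means on the fixed unit-range
#'   scale), `M`, `site_profiles` (site x cluster voxel counts) and the
#'   scalings used.
#' @export
cluster_subregions <- function(features, sites, K_range = 1:8, n_init = 5,
                               seed = 1,
                               feature_scale = c(Energy = 1,
                                                 Entropy = log(64),
                                                 Contrast = 49,
                                                 Homogeneity = 1)) {
  ok <- rowSums(!is.finite(features)) == 0
  X <- features[ok, , drop = FALSE]
  sites <- sites[ok]
  n <- nrow(X)
  if (n < min(K_range))
    stopf("clustering infeasible: %d valid voxels < smallest K (%d)",
          n, min(K_range))
  if (n < 50)
    warning(sprintf("only %d pooled voxels; subregion clustering is unstable",
                    n))
  ctr <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, sdv, `/`)
  U <- sweep(X, 2, as.numeric(feature_scale), `/`)
  K_range <- K_range[K_range <= n]
  fits <- lapply(K_range, function(K) fit_gmm(Z, K, n_init, seed))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bic)]]
  labels <- max.col(best$resp, ties.method = "first")
  key <- paste(sites, labels, sep = "\r")
  grp <- unique(key)
  means <- t(vapply(grp, function(k)
    colMeans(U[key == k, , drop = FALSE]), numeric(ncol(U))))
  parts <- do.call(rbind, strsplit(grp, "\r", fixed = TRUE))
  sub <- data.frame(site = parts[, 1], cluster = as.integer(parts[, 2]),
                    n = as.integer(table(factor(key, levels = grp))))
  site_profiles <- as.matrix(table(sites, factor(labels, levels =
                                                   seq_len(best$K))))
  structure(list(K = best$K, labels = labels, sites = sites,
                 bic = setNames(bic, K_range), subregions = sub,
                 means = means, M = nrow(sub),
                 site_profiles = site_profiles,
                 scale_center = ctr, scale_sd = sdv,
                 feature_scale = feature_scale),
            class = "subregion_model")
}

#' @export
print.subregion_model <- function(x, ...) {
  cat(sprintf("<subregion_model> K = %d clusters, %d sites, M = %d subregions\n",
              x$K, length(unique(x$sites)), x$M))
  invisible(x)
}
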