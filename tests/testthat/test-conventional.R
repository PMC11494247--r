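# The 8 per-lesion conventional features and the 13 patient-level
# statistics.

test_that("lesion_features on a uniform VOI matches the closed form", {
  dims <- c(10, 10, 10)
  sp <- c(1, 1, 1)                      # 1 mm^3 voxels
  mask <- make_box_mask(dims, c(5, 5, 4), offset = c(3, 3, 3))  # 100 voxels
  ct <- image_volume(array(35, dims), sp, modality = "CT_HU")
  pet <- image_volume(array(4.0, dims), sp, modality = "PET_SUV")
  f <- lesion_features(ct, pet, mask)
  expect_equal(f$suv_mean, 4.0)
  expect_equal(f$suv_max, 4.0)
  expect_equal(f$suv_peak, 4.0)         # uniform field -> v
  expect_equal(f$pixel_number, 100)
  expect_equal(f$tlg, 4.0 * 0.1)        # SUVmean x 0.1 cm^3
  expect_equal(f$ct_value, 35)
  expect_error(lesion_features(ct, pet, array(FALSE, dims)), "empty mask")
})

test_that("axis_lengths matches hand covariance and is rotation invariant", {
  # two voxels 10 mm apart: population variance 25 -> major 4*sqrt(25) = 20
  m <- array(FALSE, c(12, 3, 3))
  m[c(1, 11), 2, 2] <- TRUE
  ax <- axis_lengths(m, c(1, 1, 1))
  expect_equal(unname(ax["major_mm"]), 20)
  expect_true(isTRUE(attr(ax, "degenerate")))

  # sphere: major ~ minor
  sm <- make_ellipsoid_mask(c(31, 31, 31), c(1, 1, 1), c(10, 10, 10))
  axs <- axis_lengths(sm, c(1, 1, 1))
  expect_lt(abs(axs["major_mm"] - axs["minor_mm"]) / axs["major_mm"], 0.02)

  # digital ellipsoid vs analytic: continuous uniform ellipsoid with
  # semi-axes (a,b,c) has covariance eigenvalues a^2/5 >= b^2/5 >= c^2/5,
  # so axis length = 4a/sqrt(5)
  em <- make_ellipsoid_mask(c(45, 29, 21), c(0.5, 0.5, 0.5), c(10, 6, 4))
  axe <- axis_lengths(em, c(0.5, 0.5, 0.5))
  expect_lt(abs(axe["major_mm"] - 4 * 10 / sqrt(5)) / (4 * 10 / sqrt(5)), 0.05)
  expect_lt(abs(axe["minor_mm"] - 4 * 6 / sqrt(5)) / (4 * 6 / sqrt(5)), 0.05)

  # 90 degree rotation about z leaves lengths unchanged (isotropic grid)
  em2 <- aperm(em, c(2, 1, 3))
  axr <- axis_lengths(em2, c(0.5, 0.5, 0.5))
  expect_equal(unname(axr), unname(axe), tolerance = 1e-10)

  expect_error(axis_lengths(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "2 voxels")
})

test_that("suv_peak equals the brute-force sphere-search oracle", {
  set.seed(7)
  dims <- c(15, 15, 15)
  sp <- c(2, 2, 2)
  vals <- array(runif(prod(dims), 0, 10), dims)
  mask <- make_ellipsoid_mask(dims, sp, c(8, 7, 9))
  expect_equal(suv_peak(vals, mask, sp), oracle_suv_peak(vals, mask, sp))

  # single hot voxel
  vals2 <- array(0, dims)
  vals2[8, 8, 8] <- 50
  mask2 <- array(FALSE, dims); mask2[7:9, 7:9, 7:9] <- TRUE
  expect_equal(suv_peak(vals2, mask2, sp), oracle_suv_peak(vals2, mask2, sp))

  # mask smaller than the sphere: documented fallback = mean over the
  # available in-grid, in-sphere voxels
  mask3 <- array(FALSE, dims); mask3[2, 2, 2] <- TRUE
  expect_equal(suv_peak(vals, mask3, sp), oracle_suv_peak(vals, mask3, sp))
})

test_that("the 13 statistics match direct-formula oracles and edge rules", {
  # pinned examples
  expect_equal(patient_statistic(c(5, 5, 5), "Variance"), 0)
  expect_equal(patient_statistic(c(5, 5, 5), "Range"), 0)
  expect_equal(patient_statistic(c(5, 5, 5), "CV"), 0)
  expect_equal(patient_statistic(c(5, 5, 5), "CSS"), 0)
  expect_equal(patient_statistic(c(5, 5, 5), "USS"), 75)
  x <- c(1, 2, 3, 4)
  expect_equal(patient_statistic(x, "Mean"), 2.5)
  expect_equal(patient_statistic(x, "Range"), 3)
  expect_equal(patient_statistic(x, "SM"), sd(x) / 2)
  expect_equal(patient_statistic(x, "QD"), 0.75)
  # n = 2: shape statistics are missing under bias-corrected formulas
  expect_true(is.na(patient_statistic(c(1, 2), "Skewness")))
  expect_true(is.na(patient_statistic(c(1, 2), "Kurtosis")))
  expect_true(is.na(patient_statistic(c(1, 2, 3), "Kurtosis")))
  expect_false(is.na(patient_statistic(c(1, 2, 4), "Skewness")))
  # CV at mean zero is missing, never imputed
  expect_true(is.na(patient_statistic(c(-1, 1), "CV")))
  expect_error(patient_statistic(c(1, NA), "Mean"), "finite")

  # 100 random small vectors vs oracles at 1e-10 relative tolerance
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(4:9, 1)
    v <- round(rnorm(n, 50, 20), 3)
    for (s in spathet:::conv_stats) {
      got <- patient_statistic(v, s, mode_resolution = 0.5)
      want <- oracle_stat(v, s, mode_res = 0.5)
      expect_equal(got, want, tolerance = 1e-10,
                   label = sprintf("%s on rep %d", s, rep))
    }
  }
})

test_that("statistics are permutation invariant and scale equivariant", {
  set.seed(3)
  v <- rnorm(6, 40, 15)
  p <- sample(v)
  for (s in spathet:::conv_stats)
    expect_equal(patient_statistic(p, s), patient_statistic(v, s))

  c0 <- 3.7
  linear <- c("Mean", "Median", "Range", "SD", "SM")
  for (s in linear)
    expect_equal(patient_statistic(c0 * v, s), c0 * patient_statistic(v, s))
  for (s in c("Variance", "CSS", "USS"))
    expect_equal(patient_statistic(c0 * v, s), c0^2 * patient_statistic(v, s))
  for (s in c("CV", "Skewness", "Kurtosis"))
    expect_equal(patient_statistic(c0 * v, s), patient_statistic(v, s))
})

test_that("conventional block has 104 named entries with documented naming", {
  set.seed(21)
  feats <- data.frame(ct_value = rnorm(5, 40, 10),
                      minor_axis_mm = runif(5, 5, 10),
                      major_axis_mm = runif(5, 10, 20),
                      pixel_number = sample(50:500, 5),
                      tlg = runif(5, 1, 30), suv_mean = runif(5, 2, 8),
                      suv_peak = runif(5, 3, 9), suv_max = runif(5, 4, 12))
  block <- conventional_block(feats)
  expect_length(block, 104)
  expect_true(all(c("Max_SM", "Min_SM", "Vol_SM", "HU_Kurtosis",
                    "TLG_Kurtosis", "Peak_Skewness") %in% names(block)))
  expect_equal(unname(block["Max_SM"]), sd(feats$suv_max) / sqrt(5))
  expect_equal(unname(block["HU_Kurtosis"]),
               oracle_stat(feats$ct_value, "Kurtosis"))

  # identical lesions: every dispersion statistic is 0
  same <- feats[rep(1, 4), ]
  b2 <- conventional_block(same)
  for (f in spathet:::conv_features)
    for (s in c("SD", "QD", "Variance", "Range", "SM", "CSS", "CV"))
      expect_equal(unname(b2[paste(f, s, sep = "_")]), 0)

  # shuffling lesion order leaves the block unchanged
  b3 <- conventional_block(feats[sample(5), ])
  expect_equal(b3, block)
})

test_that("conventional_indicator_table emits 104 columns per patient", {
  set.seed(2)
  lt <- do.call(rbind, lapply(1:3, function(id)
    data.frame(patient_id = id, ct_value = rnorm(4, 40, 8),
               minor_axis_mm = runif(4, 5, 9), major_axis_mm = runif(4, 9, 15),
               pixel_number = sample(50:200, 4), tlg = runif(4, 1, 10),
               suv_mean = runif(4, 2, 6), suv_peak = runif(4, 2, 7),
               suv_max = runif(4, 3, 8))))
  tab <- conventional_indicator_table(lt)
  expect_equal(dim(tab), c(3, 105))   # patient_id + 104
  expect_equal(sum(grepl("^(HU|Min|Maj|Vol|TLG|Mean|Peak|Max)_", names(tab))),
               104)
})
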