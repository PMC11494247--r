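# Volume I/O, VOI extraction, the size filter and region assignment.

test_that("NIfTI round-trip is lossless (values, spacing, origin, modality)", {
  set.seed(42)
  v <- image_volume(array(rnorm(1000), c(10, 10, 10)), c(2, 2, 2),
                    c(0, 0, 0), "CT_HU")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_identical(r$values, v$values)   # max abs difference 0
  expect_identical(r$spacing_mm, v$spacing_mm)
  expect_identical(r$origin_mm, v$origin_mm)
  expect_identical(r$modality, "CT_HU")

  # anisotropic spacing survives the float32 header exactly
  va <- image_volume(array(1.0, c(4, 4, 4)), c(0.98, 0.98, 3.8),
                     c(-12.5, 3.25, 40), "PET_SUV")
  pa <- tempfile(fileext = ".nii")
  write_volume(va, pa)
  ra <- read_volume(pa)
  expect_identical(ra$spacing_mm, c(0.98, 0.98, 3.8))
  expect_identical(ra$origin_mm, c(-12.5, 3.25, 40))
  expect_identical(ra$modality, "PET_SUV")

  # integer label maps round-trip through int32
  lab <- array(sample(0:5, 60, TRUE), c(5, 4, 3))
  pl <- tempfile(fileext = ".nii.gz")
  write_volume(image_volume(lab * 1.0, c(1, 1, 1)), pl, datatype = "int32")
  expect_identical(read_volume(pl)$values, lab * 1.0)
})

test_that("malformed NIfTI input fails naming the offending field", {
  bad <- tempfile(fileext = ".nii")
  writeBin(as.integer(c(100L)), bad, size = 4L)
  expect_error(read_volume(bad), "sizeof_hdr")
  expect_error(read_volume(tempfile()), "not found")
})

test_that("extract_vois yields one VOI per label with exact counts", {
  dims <- c(8, 8, 6)
  lab <- array(0L, dims)
  lab[1:2, 1:2, 1:2] <- 1L
  lab[5:7, 5:7, 3:4] <- 2L
  lab[1:3, 6:8, 5:6] <- 3L
  ct <- image_volume(array(0, dims), c(2, 2, 2), modality = "CT_HU")
  pet <- image_volume(array(1, dims), c(2, 2, 2), modality = "PET_SUV")
  vois <- extract_vois(lab, ct, pet)
  expect_length(vois, 3)
  expect_identical(vapply(vois, `[[`, integer(1), "lesion_id"), 1:3)
  expect_identical(vapply(vois, `[[`, integer(1), "voxel_count"),
                   c(8L, 18L, 18L))
  expect_true(vois[[1]]$is_primary)
  expect_false(vois[[2]]$is_primary)
  # masks are pairwise disjoint
  expect_equal(sum(vois[[1]]$mask & vois[[2]]$mask), 0)

  # all-zero map mirrors the "no metastatic lesions" exclusion
  expect_error(extract_vois(array(0L, dims), ct, pet), "no lesions")
  # frame mismatch
  pet2 <- image_volume(array(1, dims), c(2, 2, 3), modality = "PET_SUV")
  expect_error(extract_vois(lab, ct, pet2), "frame mismatch")
  expect_error(extract_vois(array(0L, c(4, 4, 4)), ct, pet), "frame mismatch")
})

test_that("filter_vois applies the strict per-axis > 5 mm rule", {
  dims <- c(20, 20, 20)
  sp <- c(1, 1, 1)
  mk_voi <- function(id, n_vox) {
    structure(list(lesion_id = id, mask = make_box_mask(dims, n_vox),
                   region_code = NA, is_primary = id == 1,
                   voxel_count = prod(n_vox), spacing_mm = sp,
                   origin_mm = c(0, 0, 0)), class = "voi")
  }
  vois <- list(mk_voi(1L, c(4, 4, 4)),    # 4x4x4 mm -> rejected
               mk_voi(2L, c(6, 6, 6)),    # 6x6x6 mm -> kept
               mk_voi(3L, c(6, 6, 4)),    # fails one axis -> rejected
               mk_voi(4L, c(5, 5, 5)))    # exactly 5 mm: not strictly > 5
  out <- filter_vois(vois, sp, min_extent_mm = 5)
  expect_identical(vapply(out$kept, `[[`, integer(1), "lesion_id"), 2L)
  expect_setequal(out$rejected$lesion_id, c(1L, 3L, 4L))
  expect_match(out$rejected$reason[out$rejected$lesion_id == 3L], "z")

  # idempotence
  again <- filter_vois(out$kept, sp, min_extent_mm = 5)
  expect_length(again$kept, 1)
  expect_equal(nrow(again$rejected), 0)

  # spacing-dependence: same voxel counts, coarser spacing -> kept
  out2 <- filter_vois(list(mk_voi(1L, c(4, 4, 4))), c(2, 2, 2))
  expect_length(out2$kept, 1)
})

test_that("region codes partition the 3x3 grid with AR0 central, AR1 right-upper", {
  planes <- region_planes(c(30, 60), c(20, 40))
  # brute-force oracle over the 9 cells: column (L/M/R along +x = patient
  # right), row (D/M/U along +z = superior)
  probe <- expand.grid(x = c(15, 45, 75), z = c(10, 30, 50))
  oracle <- function(x, z) {
    col <- if (x < 30) "L" else if (x > 60) "R" else "M"
    row <- if (z < 20) "D" else if (z > 40) "U" else "M"
    c(LD = "AR5", LM = "AR4", LU = "AR3", MD = "AR6", MM = "AR0",
      MU = "AR2", RD = "AR7", RM = "AR8", RU = "AR1")[paste0(col, row)]
  }
  got <- mapply(region_code, probe$x, probe$z, MoreArgs = list(planes = planes))
  want <- mapply(oracle, probe$x, probe$z)
  expect_identical(unname(got), unname(want))
  expect_setequal(got, paste0("AR", 0:8))
  expect_identical(region_code(45, 30, planes), "AR0")
  expect_identical(region_code(75, 50, planes), "AR1")
  # ties exactly on a plane resolve toward the middle band
  expect_identical(region_code(30, 30, planes), "AR0")
  expect_identical(region_code(60, 40, planes), "AR0")
  expect_identical(region_code(75, 40, planes), "AR8")
})

test_that("assign_region uses the mask centroid and flags out-of-field probes", {
  dims <- c(30, 30, 30)
  sp <- c(3, 3, 2)
  planes <- region_planes(c(28, 58), c(18, 38))
  m <- make_box_mask(dims, c(3, 3, 3), offset = c(14, 14, 14))
  voi <- structure(list(lesion_id = 1L, mask = m, region_code = NA,
                        is_primary = TRUE, voxel_count = 27L,
                        spacing_mm = sp, origin_mm = c(0, 0, 0)),
                   class = "voi")
  got <- assign_region(voi, planes)
  cen <- c(mean(c(14:16) - 1) * 3, NA, mean(c(14:16) - 1) * 2)
  expect_identical(got$region_code, region_code(cen[1], cen[3], planes))
  expect_error(
    assign_region(voi, planes, grid_extent_mm = list(x = c(0, 10), z = c(0, 10))),
    "out-of-field")
})

test_that("extract -> write -> read -> extract is the identity on masks", {
  cfg <- phantom_config(n_lesions = 3L)
  p <- generate_patient(cfg, seed = 5)
  dir <- tempfile()
  write_phantom_patient(p, dir)
  ct <- read_volume(file.path(dir, "ct.nii.gz"))
  pet <- read_volume(file.path(dir, "pet.nii.gz"))
  lab <- read_volume(file.path(dir, "labels.nii.gz"))
  vois2 <- extract_vois(lab, ct, pet)
  expect_length(vois2, length(p$vois))
  for (i in seq_along(vois2)) {
    expect_identical(vois2[[i]]$voxel_count, p$vois[[i]]$voxel_count)
    expect_identical(which(vois2[[i]]$mask), which(p$vois[[i]]$mask))
  }
})
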