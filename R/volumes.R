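# VOI extraction, the >5x5x5 mm size filter, and 9-region assignment.
#
# Orientation convention (pinned): +x = patient right, +z = superior, so the
# "right upper" cell of the 3x3 abdominopelvic partition is x above the second
# sagittal plane and z above the second transverse plane.

#' Extract per-lesion volumes of interest from an integer label map
#'
#' One VOI per distinct positive label; label 0 is background. The label map
#' and both volumes must share one spatial frame. The VOI mask is the labelled
#' voxel set (in a segmented PET/CT study this is the FDG-avid solid component
#' of the lesion). Lesion 1 is flagged as the primary lesion.
#'
#' @param label_map `image_volume` (integer-valued) or 3-D integer array.
#' @param ct,pet CT and PET [image_volume()]s, co-registered.
#' @return List of `voi` objects with fields `lesion_id`, `mask`,
#'   `region_code` (`NA` until [assign_region()]), `is_primary`, `voxel_count`,
#'   `spacing_mm`, `origin_mm`.
#' @export
extract_vois <- function(label_map, ct, pet) {
  if (!inherits(ct, "image_volume") || !inherits(pet, "image_volume"))
    stopf("ct and pet must be image_volume objects")
  if (!same_frame(ct, pet))
    stopf("frame mismatch: CT and PET grids differ in shape/spacing/origin")
  lm <- if (inherits(label_map, "image_volume")) label_map$values else label_map
  if (!identical(dim(lm), dim(ct$values)))
    stopf("frame mismatch: label map and volumes differ in shape")
  if (inherits(label_map, "image_volume") && !same_frame(label_map, ct))
    stopf("frame mismatch: label map and volumes differ in spacing/origin")
  lm <- array(as.integer(round(lm)), dim = dim(lm))
  if (any(lm < 0L)) stopf("label map must be non-negative integers")
  labels <- sort(unique(lm[lm > 0L]))
  if (length(labels) == 0L)
    stopf("no lesions: label map contains no positive labels")
  lapply(labels, function(id) {
    mask <- lm == id
    structure(list(lesion_id = id, mask = mask, region_code = NA_character_,
                   is_primary = id == labels[1L],
                   voxel_count = sum(mask),
                   spacing_mm = ct$spacing_mm, origin_mm = ct$origin_mm),
              class = "voi")
  })
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi %d%s> %d voxels, region %s\n", x$lesion_id,
              if (isTRUE(x$is_primary)) " (primary)" else "",
              x$voxel_count, x$region_code))
  invisible(x)
}

# Physical bounding-box extent of a mask, per axis (mm): number of spanned
# voxels times spacing, i.e. the size of the box of voxel cubes.
mask_extent_mm <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  (apply(idx, 2, max) - apply(idx, 2, min) + 1L) * spacing_mm
}

#' Filter VOIs by minimum physical size
#'
#' A VOI is kept iff its bounding box strictly exceeds `min_extent_mm` on
#' every axis (the "greater than 5 x 5 x 5 mm" rule, read literally per axis).
#'
#' @param vois List of VOIs from [extract_vois()].
#' @param spacing_mm Voxel spacing; defaults to the VOIs' own.
#' @param min_extent_mm Threshold in mm (default 5).
#' @return List with `kept` (VOI list) and `rejected` (data.frame log with
#'   lesion_id, per-axis extents, reason). An empty `kept` list is allowed.
#' @export
filter_vois <- function(vois, spacing_mm = NULL, min_extent_mm = 5) {
  keep <- logical(length(vois))
  log <- vector("list", length(vois))
  for (i in seq_along(vois)) {
    v <- vois[[i]]
    sp <- spacing_mm %||% v$spacing_mm
    ext <- mask_extent_mm(v$mask, sp)
    keep[i] <- all(ext > min_extent_mm)
    if (!keep[i])
      log[[i]] <- data.frame(lesion_id = v$lesion_id, extent_x = ext[1],
                             extent_y = ext[2], extent_z = ext[3],
                             reason = sprintf(
                               "bounding box not > %g mm on axes: %s",
                               min_extent_mm,
                               paste(c("x", "y", "z")[ext <= min_extent_mm],
                                     collapse = ",")))
  }
  rejected <- do.call(rbind, log[!keep])
  if (is.null(rejected))
    rejected <- data.frame(lesion_id = integer(), extent_x = numeric(),
                           extent_y = numeric(), extent_z = numeric(),
                           reason = character())
  list(kept = vois[keep], rejected = rejected)
}

#' Region planes for the 9-region abdominopelvic scheme
#'
#' The abdomen is partitioned by two sagittal planes (x, mm) and two
#' transverse planes (z, mm) into a 3x3 grid of regions.
#'
#' @param x Increasing numeric length 2, sagittal plane coordinates.
#' @param z Increasing numeric length 2, transverse plane coordinates.
#' @export
region_planes <- function(x, z) {
  x <- as.numeric(x); z <- as.numeric(z)
  if (length(x) != 2 || length(z) != 2 || x[1] >= x[2] || z[1] >= z[2])
    stopf("region planes must satisfy x1 < x2 and z1 < z2")
  list(x = x, z = z)
}

#' Region code of a physical point under the 9-region scheme
#'
#' AR0 is the central (umbilical) cell; AR1 is the right-upper cell and
#' AR1-AR8 proceed clockwise (right-upper, epigastric, left-upper, left
#' flank, left-lower, hypogastric, right-lower, right flank). A point exactly
#' on a plane is assigned to the middle band (toward AR0).
#'
#' @param x,z Point coordinates in mm (+x patient right, +z superior).
#' @param planes [region_planes()].
#' @return A region code `"AR0"`..`"AR8"`.
#' @export
region_code <- function(x, z, planes) {
  col <- ifelse(x > planes$x[2], "R", ifelse(x < planes$x[1], "L", "M"))
  row <- ifelse(z > planes$z[2], "U", ifelse(z < planes$z[1], "D", "M"))
  key <- paste0(col, row)
  codes <- c(MM = "AR0", RU = "AR1", MU = "AR2", LU = "AR3", LM = "AR4",
             LD = "AR5", MD = "AR6", RD = "AR7", RM = "AR8")
  unname(codes[key])
}

# Physical centroid (mm) of a mask in its volume frame.
mask_centroid_mm <- function(mask, spacing_mm, origin_mm) {
  idx <- which(mask, arr.ind = TRUE)
  origin_mm + (colMeans(idx) - 1) * spacing_mm
}

#' Assign an abdominopelvic region code to a VOI
#'
#' Uses the VOI mask centroid (one deterministic code per lesion) and the
#' 3x3 partition of [region_code()].
#'
#' @param voi A `voi`.
#' @param planes [region_planes()].
#' @param grid_extent_mm Optional length-2 list/limits `list(x=, z=)` for the
#'   out-of-field check; defaults to no check (in-grid masks are always in
#'   field).
#' @return The VOI with `region_code` set.
#' @export
assign_region <- function(voi, planes, grid_extent_mm = NULL) {
  cen <- mask_centroid_mm(voi$mask, voi$spacing_mm, voi$origin_mm)
  if (!is.null(grid_extent_mm)) {
    if (cen[1] < grid_extent_mm$x[1] || cen[1] > grid_extent_mm$x[2] ||
        cen[3] < grid_extent_mm$z[1] || cen[3] > grid_extent_mm$z[2])
      stopf("out-of-field: VOI centroid (%.1f, %.1f, %.1f) mm outside grid",
            cen[1], cen[2], cen[3])
  }
  voi$region_code <- region_code(cen[1], cen[3], planes)
  voi
}
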