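# Synthetic multi-lesion PET/CT phantom cohorts with known ground-truth
# heterogeneity. Lesions are axis-aligned ellipsoidal cystic-solid composites:
# the outer shell is the FDG-avid solid component (this is the VOI), the core
# is cystic (low SUV, low HU). Each lesion carries a texture class whose
# smoothed-random-field HU modulation drives the downstream Haralick
# signature; the number of distinct classes per patient is the ground-truth
# spatial heterogeneity.

#' Define a lesion texture class
#'
#' A class is a stationary smoothed random field: seeded white noise
#' convolved with a Gaussian kernel of the given correlation length, scaled
#' to `amplitude` (HU standard deviation) and shifted by `base_offset`.
#'
#' @param name Class label.
#' @param correlation_length_mm Spatial smoothness (> 0).
#' @param amplitude HU modulation SD (>= 0).
#' @param base_offset HU shift (absorbed by per-VOI min-max rescaling;
#'   retained for CT realism).
#' @export
texture_class <- function(name, correlation_length_mm, amplitude,
                          base_offset = 0) {
  if (correlation_length_mm <= 0) stopf("correlation_length_mm must be > 0")
  if (amplitude < 0) stopf("amplitude must be >= 0")
  structure(list(name = name,
                 correlation_length_mm = correlation_length_mm,
                 amplitude = amplitude, base_offset = base_offset),
            class = "texture_class")
}

#' Default texture classes
#'
#' Four classes chosen to be separable in windowed GLCM statistics at the
#' default settings: they differ in spatial correlation length, the robust
#' driver of co-occurrence statistics at unit offsets (fine fields have high
#' Contrast / low Homogeneity, coarse fields the opposite), with amplitude
#' well above the scanner noise floor throughout.
#'
#' @export
default_texture_classes <- function() {
  list(texture_class("white", 0.6, 60, 0),
       texture_class("fine", 2.5, 60, 5),
       texture_class("coarse", 5.0, 60, -5),
       texture_class("blob", 9.0, 60, 10))
}

#' Phantom configuration
#'
#' Defaults state the emulated world: 2 mm isotropic grids of 52 x 52 x 40
#' voxels (104 x 104 x 80 mm field), 5 lesions per patient (desk-scale
#' stand-in for the clinical median of 6-7 lesions), ellipsoid semi-axes
#' 8-13 mm (well above the 5 mm size filter), 40-70% solid fraction
#' realised as a thick crescent around an off-centre cystic core, solid
#' SUV 4-10 vs
#' cystic 0.5-1.5, solid HU 30-50 vs cystic 5-15, 5 HU scanner noise. The
#' resistance label is Bernoulli(plogis(intercept + slope * mixture
#' entropy)); with `intercept = NA` the intercept is calibrated so the
#' expected prevalence matches `target_prevalence` (default 0.35, the
#' clinical resistance range of roughly 32-39%).
#'
#' @param grid_shape Integer length 3.
#' @param spacing_mm Positive numeric length 3 (mm).
#' @param n_lesions Lesions per patient, in 2..10.
#' @param region_planes [region_planes()]; defaults to thirds of the field.
#' @param lesion_radius_range_mm Semi-axis range (mm).
#' @param solid_fraction_range Fraction of lesion volume that is solid.
#' @param texture_classes List of [texture_class()] objects.
#' @param suv_solid_range,suv_cystic_range SUV intervals; solid must lie
#'   strictly above cystic.
#' @param hu_solid_range,hu_cystic_range HU intervals.
#' @param noise_sd Additive CT noise SD (HU).
#' @param pet_noise_sd Additive PET noise SD (SUV).
#' @param label_link `c(intercept, slope)` of the logistic link on the true
#'   mixture entropy; `intercept = NA` triggers calibration.
#' @param target_prevalence Expected resistance prevalence used when
#'   calibrating the intercept.
#' @param class_assignment `"variable"` (default: the number of distinct
#'   classes per patient is uniform on 1..K, then assigned round-robin over
#'   a random class subset - patients genuinely differ in texture-phenotype
#'   diversity), `"random"` (iid uniform over classes) or `"balanced"`
#'   (round-robin over all classes, then shuffled).
#' @param background_hu,background_suv Background tissue values.
#' @param seed Default seed stored with the config.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(52L, 52L, 40L),
                           spacing_mm = c(2, 2, 2),
                           n_lesions = 5L,
                           region_planes = NULL,
                           lesion_radius_range_mm = c(8, 13),
                           solid_fraction_range = c(0.4, 0.7),
                           texture_classes = default_texture_classes(),
                           suv_solid_range = c(4, 10),
                           suv_cystic_range = c(0.5, 1.5),
                           hu_solid_range = c(30, 50),
                           hu_cystic_range = c(5, 15),
                           noise_sd = 5,
                           pet_noise_sd = 0.1,
                           label_link = c(intercept = NA, slope = 2),
                           target_prevalence = 0.35,
                           class_assignment = c("variable", "random", "balanced"),
                           background_hu = 20,
                           background_suv = 0.5,
                           seed = 1L) {
  class_assignment <- match.arg(class_assignment)
  if (n_lesions < 2L || n_lesions > 10L)
    stopf("n_lesions must lie in [2, 10]")
  chk_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2]) stopf("%s must be a non-empty interval", nm)
  }
  chk_range(lesion_radius_range_mm, "lesion_radius_range_mm")
  chk_range(solid_fraction_range, "solid_fraction_range")
  chk_range(suv_solid_range, "suv_solid_range")
  chk_range(suv_cystic_range, "suv_cystic_range")
  chk_range(hu_solid_range, "hu_solid_range")
  chk_range(hu_cystic_range, "hu_cystic_range")
  if (suv_solid_range[1] <= suv_cystic_range[2])
    stopf("solid SUV range must lie above the cystic SUV range")
  fov <- grid_shape * spacing_mm
  if (is.null(region_planes))
    region_planes <- region_planes(fov[1] * c(1, 2) / 3, fov[3] * c(1, 2) / 3)
  cfg <- structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    n_lesions = as.integer(n_lesions), region_planes = region_planes,
    lesion_radius_range_mm = lesion_radius_range_mm,
    solid_fraction_range = solid_fraction_range,
    texture_classes = texture_classes,
    suv_solid_range = suv_solid_range, suv_cystic_range = suv_cystic_range,
    hu_solid_range = hu_solid_range, hu_cystic_range = hu_cystic_range,
    noise_sd = noise_sd, pet_noise_sd = pet_noise_sd,
    label_link = c(intercept = unname(label_link[1]),
                   slope = unname(label_link[2])),
    target_prevalence = target_prevalence,
    class_assignment = class_assignment,
    background_hu = background_hu, background_suv = background_suv,
    seed = as.integer(seed)), class = "phantom_config")
  if (is.na(cfg$label_link["intercept"]))
    cfg$label_link["intercept"] <- calibrate_label_intercept(cfg)
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(paste0("<phantom_config> %s voxels @ %s mm, %d lesions, ",
                     "%d texture classes (%s), link = plogis(%.3f + %.2f*H)\n"),
              paste(x$grid_shape, collapse = "x"),
              paste(x$spacing_mm, collapse = "x"), x$n_lesions,
              length(x$texture_classes), x$class_assignment,
              x$label_link["intercept"], x$label_link["slope"]))
  invisible(x)
}

# Exact distribution of the class-mixture entropy under the configured
# assignment scheme, used to calibrate the label-link intercept so that
# E[plogis(a + slope*H)] equals the target prevalence.
entropy_distribution <- function(n_lesions, n_classes, class_assignment) {
  if (class_assignment == "balanced" || n_classes == 1) {
    counts <- table(rep(seq_len(n_classes), length.out = n_lesions))
    return(data.frame(H = shannon_entropy(as.numeric(counts)), p = 1))
  }
  if (class_assignment == "variable") {
    H <- vapply(seq_len(n_classes), function(kk)
      shannon_entropy(as.numeric(table(rep(seq_len(kk),
                                           length.out = n_lesions)))),
      numeric(1))
    return(data.frame(H = H, p = rep(1 / n_classes, n_classes)))
  }
  grids <- rep(list(0:n_lesions), n_classes - 1)
  combos <- as.matrix(expand.grid(grids))
  combos <- combos[rowSums(combos) <= n_lesions, , drop = FALSE]
  counts <- cbind(combos, n_lesions - rowSums(combos))
  logp <- lgamma(n_lesions + 1) - rowSums(lgamma(counts + 1)) -
    n_lesions * log(n_classes)
  H <- apply(counts, 1, shannon_entropy)
  agg <- tapply(exp(logp), round(H, 12), sum)
  data.frame(H = as.numeric(names(agg)), p = as.numeric(agg))
}

calibrate_label_intercept <- function(cfg) {
  dist <- entropy_distribution(cfg$n_lesions, length(cfg$texture_classes),
                               cfg$class_assignment)
  slope <- cfg$label_link["slope"]
  f <- function(a) sum(dist$p * plogis(a + slope * dist$H)) -
    cfg$target_prevalence
  unname(uniroot(f, c(-30, 30), tol = 1e-10)$root)
}

gauss_kernel <- function(sigma) {
  if (sigma <= 1e-9) return(1)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-hw:hw) / sigma)^2)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3-D array (truncated, renormalized at
# the boundary).
smooth_field <- function(a, sigma_vox) {
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_vox[ax])
    if (length(k) == 1) next
    hw <- (length(k) - 1) / 2
    n <- dim(a)[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - hw):min(n, i + hw)
      w <- k[j - i + hw + 1]
      K[i, j] <- w / sum(w)
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(a, perm)
    dm <- dim(a)
    a <- array(K %*% matrix(a, dm[1]), dm)
    a <- aperm(a, order(perm))
  }
  a
}

# Sample disjoint lesion geometries (centres + semi-axes in mm) by rejection;
# bounded retries so an undersized grid fails loudly.
place_lesions <- function(cfg) {
  fov <- cfg$grid_shape * cfg$spacing_mm
  rr <- cfg$lesion_radius_range_mm
  centres <- matrix(NA_real_, cfg$n_lesions, 3)
  semiax <- matrix(NA_real_, cfg$n_lesions, 3)
  margin <- 2
  for (i in seq_len(cfg$n_lesions)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      ax <- runif(3, rr[1], rr[2])
      rmax <- max(ax)
      lo <- rmax + margin
      hi <- fov - rmax - margin
      if (any(hi <= lo))
        stopf("lesion placement failed: grid too small for lesion radius %.1f mm",
              rmax)
      cen <- runif(3, lo, hi)
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (sqrt(sum((cen - centres[j, ])^2)) <=
            rmax + max(semiax[j, ]) + 1) { ok <- FALSE; break }
      }
      if (ok) {
        centres[i, ] <- cen
        semiax[i, ] <- ax
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("lesion placement failed after bounded retries (lesion %d of %d): grid too crowded",
            i, cfg$n_lesions)
  }
  list(centres = centres, semiax = semiax)
}

#' Generate one synthetic PET/CT patient
#'
#' Deterministic under (config, seed): identical inputs give bit-identical
#' volumes and truth.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed (default: the config's).
#' @return List with `ct`, `pet` ([image_volume()]s), `label_map`
#'   (integer `image_volume`; the labelled voxels are the solid components,
#'   i.e. the VOIs), `vois` (region-coded VOI list), and `truth` (list with
#'   per-lesion table and patient-level ground truth incl. `resistance`).
#' @export
generate_patient <- function(config, seed = config$seed) {
  with_seed(seed, generate_patient_impl(config, seed))
}

generate_patient_impl <- function(cfg, seed) {
  dims <- cfg$grid_shape
  sp <- cfg$spacing_mm
  geo <- place_lesions(cfg)
  n <- cfg$n_lesions
  k <- length(cfg$texture_classes)
  cls_idx <- switch(cfg$class_assignment,
    random = sample.int(k, n, replace = TRUE),
    balanced = sample(rep(seq_len(k), length.out = n)),
    variable = {
      kk <- sample.int(k, 1)
      chosen <- sample.int(k, kk)
      sample(rep(chosen, length.out = n))
    })

  # voxel-centre coordinate grids (mm)
  xs <- (seq_len(dims[1]) - 1) * sp[1]
  ys <- (seq_len(dims[2]) - 1) * sp[2]
  zs <- (seq_len(dims[3]) - 1) * sp[3]

  ct <- array(cfg$background_hu, dim = dims)
  pet <- array(cfg$background_suv, dim = dims)
  labels <- array(0L, dim = dims)
  lesion_rows <- vector("list", n)

  for (i in seq_len(n)) {
    cen <- geo$centres[i, ]; ax <- geo$semiax[i, ]
    cl <- cfg$texture_classes[[cls_idx[i]]]
    solid_frac <- runif(1, cfg$solid_fraction_range[1],
                        cfg$solid_fraction_range[2])
    core_scale <- (1 - solid_frac)^(1 / 3)
    hu_solid <- runif(1, cfg$hu_solid_range[1], cfg$hu_solid_range[2])
    hu_cyst <- runif(1, cfg$hu_cystic_range[1], cfg$hu_cystic_range[2])
    suv_solid <- runif(1, cfg$suv_solid_range[1], cfg$suv_solid_range[2])
    suv_cyst <- runif(1, cfg$suv_cystic_range[1], cfg$suv_cystic_range[2])

    # bounding box (voxel indices) of the full ellipsoid
    i0 <- pmax(1L, floor((cen - ax) / sp) + 1L)
    i1 <- pmin(dims, ceiling((cen + ax) / sp) + 1L)
    bx <- xs[i0[1]:i1[1]]; by <- ys[i0[2]:i1[2]]; bz <- zs[i0[3]:i1[3]]
    q <- outer(((bx - cen[1]) / ax[1])^2,
               ((by - cen[2]) / ax[2])^2, `+`)
    q <- outer(q, ((bz - cen[3]) / ax[3])^2, `+`)
    full <- q <= 1
    # off-centre cystic core: a scaled copy of the ellipsoid shifted inside
    # it, so the solid component is a thick crescent rather than a thin
    # uniform shell (windowed texture needs interior voxels)
    dirv <- rnorm(3)
    dirv <- dirv / sqrt(sum(dirv^2))
    delta <- dirv * 0.9 * (1 - core_scale) * ax
    ccen <- cen + delta
    cax <- ax * core_scale
    qc <- outer(((bx - ccen[1]) / cax[1])^2,
                ((by - ccen[2]) / cax[2])^2, `+`)
    qc <- outer(qc, ((bz - ccen[3]) / cax[3])^2, `+`)
    core <- qc <= 1
    shell <- full & !core
    if (!any(shell)) next

    # class texture field on the box
    sigma_vox <- cl$correlation_length_mm / sp
    field <- smooth_field(array(rnorm(length(full)), dim = dim(full)),
                          sigma_vox)
    sdv <- sd(field)
    if (sdv > 0) field <- field / sdv

    sub_ct <- ct[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    sub_pet <- pet[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    sub_lab <- labels[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    sub_ct[shell] <- hu_solid + cl$base_offset + cl$amplitude * field[shell]
    sub_ct[core] <- hu_cyst
    sub_pet[shell] <- suv_solid
    sub_pet[core] <- suv_cyst
    sub_lab[shell] <- i
    ct[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub_ct
    pet[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub_pet
    labels[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub_lab

    lesion_rows[[i]] <- data.frame(
      lesion_id = i, class = cl$name,
      region_code = region_code(cen[1], cen[3], cfg$region_planes),
      center_x = cen[1], center_y = cen[2], center_z = cen[3],
      semi_a = ax[1], semi_b = ax[2], semi_c = ax[3],
      solid_fraction = solid_frac)
  }

  ct <- ct + rnorm(length(ct), sd = cfg$noise_sd)
  pet <- pmax(pet + rnorm(length(pet), sd = cfg$pet_noise_sd), 0)

  lesions <- do.call(rbind, lesion_rows)
  counts <- table(lesions$class)
  mixture_entropy <- shannon_entropy(as.numeric(counts))
  p_resist <- unname(plogis(cfg$label_link["intercept"] +
                              cfg$label_link["slope"] * mixture_entropy))
  resistance <- rbinom(1, 1, p_resist)

  # synthetic clinical covariate stand-ins (independent of the imaging)
  clinical <- data.frame(
    age = round(rnorm(1, 54.6, 9.3)),
    ca125 = round(rlnorm(1, log(867), 0.9), 1),
    figo_stage = sample(2:4, 1, prob = c(0.015, 0.67, 0.315)),
    sur_status = sample(0:2, 1, prob = c(0.58, 0.21, 0.21)),
    ascites = sample(0:2, 1, prob = c(0.05, 0.28, 0.67)),
    ln_pelvic = rbinom(1, 1, 0.33), ln_mid = rbinom(1, 1, 0.33),
    ln_upper = rbinom(1, 1, 0.31), ln_distant = rbinom(1, 1, 0.14),
    num_ar = length(unique(lesions$region_code)))

  ctv <- image_volume(ct, sp, c(0, 0, 0), "CT_HU")
  petv <- image_volume(pet, sp, c(0, 0, 0), "PET_SUV")
  labv <- structure(list(values = labels, spacing_mm = sp,
                         origin_mm = c(0, 0, 0), modality = "CT_HU"),
                    class = "image_volume")
  vois <- extract_vois(labv, ctv, petv)
  vois <- lapply(vois, assign_region, planes = cfg$region_planes)

  list(ct = ctv, pet = petv, label_map = labv, vois = vois,
       truth = list(seed = seed, lesions = lesions,
                    n_distinct_classes = length(counts),
                    mixture_entropy = mixture_entropy,
                    p_resist = p_resist, resistance = resistance,
                    clinical = clinical))
}

#' Generate a phantom cohort
#'
#' Per-patient seeds are derived from the master seed by a counter-based
#' scheme, so patient i is reproducible independently of generation order.
#' Volumes are not retained by default (regenerate any patient with
#' [cohort_patient()]); the truth table always is.
#'
#' @param n_patients Integer >= 2.
#' @param config A [phantom_config()].
#' @param seed Master seed.
#' @param keep_volumes Retain full patient objects (memory-heavy).
#' @return `phantom_cohort`: list with `config`, `seed`, `patient_seeds`,
#'   `truth` (one row per patient: ground truth + clinical stand-ins), and
#'   optionally `patients`.
#' @export
generate_cohort <- function(n_patients, config, seed = config$seed,
                            keep_volumes = FALSE) {
  if (n_patients < 2) stopf("n_patients must be >= 2")
  patient_seeds <- vapply(seq_len(n_patients), function(i)
    derive_seed(seed, i), integer(1))
  rows <- vector("list", n_patients)
  patients <- if (keep_volumes) vector("list", n_patients) else NULL
  for (i in seq_len(n_patients)) {
    p <- generate_patient(config, patient_seeds[i])
    rows[[i]] <- cbind(data.frame(patient_id = i, seed = patient_seeds[i],
                                  n_lesions = nrow(p$truth$lesions),
                                  n_distinct_classes = p$truth$n_distinct_classes,
                                  mixture_entropy = p$truth$mixture_entropy,
                                  p_resist = p$truth$p_resist,
                                  resistance = p$truth$resistance),
                       p$truth$clinical)
    if (keep_volumes) patients[[i]] <- p
  }
  structure(list(config = config, seed = seed,
                 patient_seeds = patient_seeds,
                 truth = do.call(rbind, rows), patients = patients),
            class = "phantom_cohort")
}

#' Regenerate one cohort patient from its stored seed
#' @param cohort A [generate_cohort()] result.
#' @param i Patient index.
#' @export
cohort_patient <- function(cohort, i) {
  if (!is.null(cohort$patients)) return(cohort$patients[[i]])
  generate_patient(cohort$config, cohort$patient_seeds[i])
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients, prevalence %.2f, master seed %d\n",
              nrow(x$truth), mean(x$truth$resistance), x$seed))
  invisible(x)
}

#' Write a phantom patient to disk
#'
#' CT/PET volumes and the integer label map as NIfTI (.nii.gz), the lesion
#' truth table as CSV, and the configuration echoed as a key=value file.
#'
#' @param patient A [generate_patient()] result.
#' @param dir Output directory (created if needed).
#' @export
write_phantom_patient <- function(patient, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(patient$ct, file.path(dir, "ct.nii.gz"))
  write_volume(patient$pet, file.path(dir, "pet.nii.gz"))
  write_volume(patient$label_map, file.path(dir, "labels.nii.gz"),
               datatype = "int32")
  write.csv(patient$truth$lesions, file.path(dir, "lesions.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Echo a phantom configuration as a key=value file
#' @param config A [phantom_config()].
#' @param path Output file.
#' @export
write_phantom_config <- function(config, path) {
  fmt <- function(x) paste(format(x, digits = 10), collapse = ",")
  lines <- c(
    paste0("grid_shape=", fmt(config$grid_shape)),
    paste0("spacing_mm=", fmt(config$spacing_mm)),
    paste0("n_lesions=", config$n_lesions),
    paste0("region_planes_x=", fmt(config$region_planes$x)),
    paste0("region_planes_z=", fmt(config$region_planes$z)),
    paste0("lesion_radius_range_mm=", fmt(config$lesion_radius_range_mm)),
    paste0("solid_fraction_range=", fmt(config$solid_fraction_range)),
    paste0("texture_classes=", paste(vapply(config$texture_classes, function(cl)
      sprintf("%s:%g:%g:%g", cl$name, cl$correlation_length_mm,
              cl$amplitude, cl$base_offset), character(1)), collapse = ";")),
    paste0("suv_solid_range=", fmt(config$suv_solid_range)),
    paste0("suv_cystic_range=", fmt(config$suv_cystic_range)),
    paste0("hu_solid_range=", fmt(config$hu_solid_range)),
    paste0("hu_cystic_range=", fmt(config$hu_cystic_range)),
    paste0("noise_sd=", config$noise_sd),
    paste0("pet_noise_sd=", config$pet_noise_sd),
    paste0("label_link=", fmt(config$label_link)),
    paste0("class_assignment=", config$class_assignment),
    paste0("seed=", config$seed))
  writeLines(lines, path)
  invisible(path)
}
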