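# End-to-end extraction: VOIs -> conventional block (104) + texture block
# (3) = the 107-entry indicator vector per patient, and cohort tables ready
# for modeling.

#' Full 107-entry indicator vector for one patient
#'
#' Extracts VOIs from the label map, applies the > `min_extent_mm` size
#' filter, assigns region codes, computes the 104 conventional indicators
#' and the 3 texture indicators.
#'
#' @param ct,pet Co-registered [image_volume()]s.
#' @param label_map Integer label map (`image_volume` or array).
#' @param planes [region_planes()] for region coding (optional).
#' @param min_extent_mm Size-filter threshold (default 5).
#' @param K_range,n_init,seed,window_radius Texture-chain settings.
#' @return List: `indicators` (named length-107 vector), `vois`,
#'   `lesion_features` (per-VOI table), `texture` (full texture output),
#'   `rejected` (filter log).
#' @export
patient_indicators <- function(ct, pet, label_map, planes = NULL,
                               min_extent_mm = 5, K_range = 1:8, n_init = 5,
                               seed = 1, window_radius = 2) {
  vois <- extract_vois(label_map, ct, pet)
  flt <- filter_vois(vois, ct$spacing_mm, min_extent_mm)
  vois <- flt$kept
  if (length(vois) < 2)
    stopf("fewer than 2 VOIs survive the size filter")
  if (!is.null(planes))
    vois <- lapply(vois, assign_region, planes = planes)
  feats <- do.call(rbind, lapply(vois, function(v)
    lesion_features(ct, pet, v$mask)))
  feats$lesion_id <- vapply(vois, `[[`, integer(1), "lesion_id")
  feats$region_code <- vapply(vois, `[[`, character(1), "region_code")
  conv <- conventional_block(feats)
  tex <- texture_indicators(ct, vois, K_range = K_range, n_init = n_init,
                            seed = seed, window_radius = window_radius)
  list(indicators = c(conv, tex$indicators), vois = vois,
       lesion_features = feats, texture = tex, rejected = flt$rejected)
}

#' Indicator table for a phantom cohort
#'
#' Regenerates each patient from its stored seed, extracts the 107
#' indicators, and binds them to the clinical stand-ins and the resistance
#' label from the truth table.
#'
#' @param cohort A [generate_cohort()] result.
#' @param K_range,n_init,window_radius Texture-chain settings (smaller
#'   `K_range`/`n_init` trade BIC search breadth for speed on large cohorts).
#' @param verbose Print progress every 25 patients.
#' @return data.frame: `patient_id`, clinical columns, 104 + 3 indicator
#'   columns, `resistance`.
#' @export
cohort_indicator_table <- function(cohort, K_range = 1:8, n_init = 5,
                                   window_radius = 2, verbose = FALSE) {
  n <- nrow(cohort$truth)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- cohort_patient(cohort, i)
    pi <- patient_indicators(p$ct, p$pet, p$label_map,
                             planes = cohort$config$region_planes,
                             K_range = K_range, n_init = n_init,
                             seed = cohort$patient_seeds[i],
                             window_radius = window_radius)
    rows[[i]] <- as.data.frame(c(list(patient_id = i),
                                 as.list(pi$indicators)))
    if (verbose && i %% 25 == 0) message(sprintf("  %d / %d patients", i, n))
  }
  ind <- do.call(rbind, rows)
  clin_cols <- c("age", "ca125", "figo_stage", "sur_status", "ascites",
                 "ln_pelvic", "ln_mid", "ln_upper", "ln_distant", "num_ar")
  cbind(ind[, "patient_id", drop = FALSE],
        cohort$truth[ind$patient_id, clin_cols],
        ind[, setdiff(colnames(ind), "patient_id")],
        resistance = cohort$truth$resistance[ind$patient_id])
}

#' Write an indicator table as CSV
#' @param table A [cohort_indicator_table()] result.
#' @param path Output path.
#' @export
write_indicator_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
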