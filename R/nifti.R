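#' Construct a 3-D image volume
#'
#' Container for one scalar volume on a regular grid: CT in Hounsfield units
#' or PET in standardized uptake values (SUV). The spatial frame follows the
#' NIfTI RAS convention: +x = patient right, +y = anterior, +z = superior,
#' with `origin_mm` at the centre of voxel (1,1,1).
#'
#' @param values 3-D numeric array.
#' @param spacing_mm positive numeric length 3, voxel size per axis (mm).
#' @param origin_mm numeric length 3, position of the first voxel centre (mm).
#' @param modality `"CT_HU"` or `"PET_SUV"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                         modality = c("CT_HU", "PET_SUV")) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L) stopf("values must be a 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stopf("spacing_mm must be 3 strictly positive finite numbers")
  if (any(!is.finite(values))) stopf("values must be finite")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm), modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, origin %s mm\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ",")))
  invisible(x)
}

# Two volumes share a frame when shape, spacing and origin agree.
same_frame <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol
}

nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

#' Write a volume as NIfTI-1
#'
#' Minimal single-file NIfTI-1 (.nii or .nii.gz) writer. The sform carries
#' spacing and origin (axis-aligned, RAS); the modality string is stored in
#' the `descrip` header field and recovered by [read_volume()]. By default
#' volumes are stored as float64 so write/read round-trips are bit-exact;
#' integer label maps should use `datatype = "int32"`.
#'
#' @param vol An [image_volume()] (or a plain integer/numeric 3-D array for
#'   label maps, in which case spacing/origin default to 1 mm / 0).
#' @param path Output path; compressed when it ends in `.gz`.
#' @param datatype One of `"float64"`, `"float32"`, `"int32"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         datatype = c("float64", "float32", "int32", "int16")) {
  datatype <- match.arg(datatype)
  if (is.array(vol) && !inherits(vol, "image_volume"))
    vol <- image_volume(vol * 1.0, c(1, 1, 1), c(0, 0, 0), "CT_HU")
  dt <- switch(datatype, float64 = 64L, float32 = 16L, int32 = 8L,
               int16 = 4L)
  size <- switch(datatype, float64 = 8L, float32 = 4L, int32 = 4L, int16 = 2L)
  dims <- dim(vol$values)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, sz) writeBin(x, con, size = sz, endian = "little")
  pad <- function(s, n) {
    r <- charToRaw(s)
    c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r))))
  }
  wb(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wb(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  wb(c(0, 0, 0), 4L)                             # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(dt, 2L)                                     # datatype
  wb(8L * size, 2L)                              # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(c(1, vol$spacing_mm, 0, 0, 0, 0), 4L)       # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  wb(0L, 2L); writeBin(raw(2L), con)             # slice_end, slice_code+units
  wb(c(0, 0, 0, 0), 4L)                          # cal_max..toffset
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(pad(vol$modality, 80L), con)          # descrip
  writeBin(raw(24L), con)                        # aux_file
  wb(c(0L, 1L), 2L)                              # qform_code=0, sform_code=1
  wb(c(0, 0, 0), 4L)                             # quatern_b,c,d
  wb(vol$origin_mm, 4L)                          # qoffset_x,y,z
  wb(c(vol$spacing_mm[1], 0, 0, vol$origin_mm[1]), 4L)  # srow_x
  wb(c(0, vol$spacing_mm[2], 0, vol$origin_mm[2]), 4L)  # srow_y
  wb(c(0, 0, vol$spacing_mm[3], vol$origin_mm[3]), 4L)  # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)    # magic
  writeBin(raw(4L), con)                         # extension flag
  if (datatype %in% c("int32", "int16")) {
    wb(as.integer(round(vol$values)), size)
  } else {
    wb(as.numeric(vol$values), size)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Counterpart of [write_volume()]. Supports uint8/int16/int32/float32/float64
#' single-file NIfTI-1, plain or gzipped, either endianness, with axis-aligned
#' sform or qoffset origin and `scl_slope`/`scl_inter` scaling. Spacing and
#' origin are rounded to 7 significant digits (the precision the format's
#' float32 header fields can carry) so values stated at that precision
#' round-trip exactly.
#'
#' @param path File path (.nii or .nii.gz).
#' @param modality Optional override; by default recovered from `descrip`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- gzfile(path, "rb")   # gzfile reads plain files transparently
  on.exit(close(con))
  endian <- "little"
  rb <- function(what, n, sz, signed = TRUE)
    readBin(con, what, n = n, size = sz, endian = endian, signed = signed)
  hdr_size <- rb("integer", 1L, 4L)
  if (!identical(hdr_size, 348L)) {
    endian <- "big"
    if (!identical(rawToInt_swap(hdr_size), 348L))
      stopf("malformed NIfTI header: sizeof_hdr = %s (expected 348)", hdr_size)
  }
  invisible(rb("raw", 36L, 1L))
  dim8 <- rb("integer", 8L, 2L)
  ndim <- dim8[1]
  if (ndim < 3L || (ndim > 3L && any(dim8[5:(ndim + 1L)] > 1L)))
    stopf("malformed NIfTI header: dim[0] = %d (only 3-D supported)", ndim)
  dims <- dim8[2:4]
  invisible(rb("numeric", 3L, 4L)); invisible(rb("integer", 1L, 2L))
  dtype <- rb("integer", 1L, 2L)
  row <- match(dtype, nifti_datatypes$code)
  if (is.na(row))
    stopf("malformed NIfTI header: unsupported datatype code %d", dtype)
  invisible(rb("integer", 2L, 2L))
  pixdim <- rb("numeric", 8L, 4L)
  vox_offset <- rb("numeric", 1L, 4L)
  scl <- rb("numeric", 2L, 4L)
  invisible(rb("integer", 1L, 2L)); invisible(rb("raw", 2L, 1L))
  invisible(rb("numeric", 4L, 4L)); invisible(rb("integer", 2L, 4L))
  dr <- rb("raw", 80L, 1L)
  nul <- which(dr == as.raw(0))
  descrip <- rawToChar(if (length(nul)) dr[seq_len(nul[1] - 1L)] else dr)
  invisible(rb("raw", 24L, 1L))
  invisible(rb("integer", 1L, 2L))
  sform_code <- rb("integer", 1L, 2L)
  invisible(rb("numeric", 3L, 4L))
  qoffset <- rb("numeric", 3L, 4L)
  srow <- matrix(rb("numeric", 12L, 4L), nrow = 3L, byrow = TRUE)
  invisible(rb("raw", 16L, 1L))
  magic <- rawToChar(rb("raw", 3L, 1L))
  if (!magic %in% c("n+1", "ni1"))
    stopf("malformed NIfTI header: magic = '%s'", magic)

  if (sform_code > 0L) {
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6 * max(abs(srow[, 1:3]))))
      stopf("malformed NIfTI header: srow is not axis-aligned")
    spacing <- abs(diag(srow[, 1:3]))
    origin <- srow[, 4]
  } else {
    spacing <- pixdim[2:4]
    origin <- qoffset
  }
  if (any(spacing <= 0))
    stopf("malformed NIfTI header: non-positive pixdim")
  spacing <- signif(spacing, 7)
  origin <- ifelse(origin == 0, 0, signif(origin, 7))

  seek(con, where = max(vox_offset, 352), origin = "start")
  n <- prod(dims)
  info <- nifti_datatypes[row, ]
  vals <- rb(info$what, n, info$size, signed = info$signed)
  if (length(vals) < n) stopf("malformed NIfTI file: truncated data section")
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  arr <- array(as.numeric(vals), dim = dims)
  mod <- modality %||% (if (descrip %in% c("CT_HU", "PET_SUV")) descrip
                        else "CT_HU")
  image_volume(arr, spacing, origin, mod)
}

# Byte-swap a little-endian-read int32 (header endianness probe).
rawToInt_swap <- function(x) {
  r <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(r), "integer", size = 4L, endian = "little")
}
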