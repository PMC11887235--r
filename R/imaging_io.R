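#' Load a 3D volume from NIfTI or a DICOM series directory
#'
#' Intensity values are read as stored (promoted to double, never
#' rescaled).  NIfTI arrays arrive in (x, y, z) order and are permuted so
#' that the volume is indexed `[slice, row, col]` with the slice axis the
#' NIfTI z axis.  DICOM directories are read slice by slice and ordered
#' by SliceLocation (0020,1041), ties broken by InstanceNumber
#' (0020,0013), giving a deterministic slice order.
#'
#' @param path file path (NIfTI) or directory path (DICOM series).
#' @param format `"nifti"` or `"dicom_dir"`.
#' @return An [mri_volume()].
#' @export
load_volume <- function(path, format = c("nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) stop("load_volume: no such file: ", path)
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3L)
      stop("load_volume: expected a 3D payload, got ", length(dim(a)), "D")
    pd <- RNifti::pixdim(img)
    spacing <- if (length(pd) >= 3 && all(pd[1:3] > 0)) pd[c(3, 2, 1)] else NULL
    mri_volume(aperm(a, c(3, 2, 1)), spacing = spacing)
  } else {
    if (!dir.exists(path)) stop("load_volume: no such directory: ", path)
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop("load_volume: empty DICOM directory: ", path)
    slices <- lapply(files, read_dicom_slice)
    loc <- vapply(slices, function(s) s$slice_location, numeric(1))
    ins <- vapply(slices, function(s) s$instance_number, numeric(1))
    ord <- order(loc, ins)
    slices <- slices[ord]
    dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("load_volume: inconsistent slice shapes in DICOM series")
    vox <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
    for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$pixels
    sp <- slices[[1]]$pixel_spacing
    spacing <- if (!is.null(sp) && length(slices) > 1) {
      dz <- abs(diff(sort(loc)))
      dz <- if (all(dz > 0)) stats::median(dz) else 1
      c(dz, sp)
    } else NULL
    mri_volume(vox, spacing = spacing)
  }
}

# --- minimal DICOM support -------------------------------------------------
# Scope: single-frame uncompressed grayscale slices in explicit-VR
# little-endian transfer syntax, which covers the synthetic series used in
# the test-suite and simple scanner exports.  Compressed transfer syntaxes
# and sequences are out of scope.

dicom_tag <- function(group, elem) sprintf("%04X%04X", group, elem)

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("read_dicom_slice: not a DICOM part-10 file: ", path)
  pos <- 133L
  fields <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw)) {
    group <- readBin(raw[pos:(pos + 1L)], "integer", size = 2, signed = FALSE,
                     endian = "little")
    elem <- readBin(raw[(pos + 2L):(pos + 3L)], "integer", size = 2,
                    signed = FALSE, endian = "little")
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- readBin(raw[(pos + 8L):(pos + 11L)], "integer", size = 4,
                     endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6L):(pos + 7L)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      vstart <- pos + 8L
    }
    if (len < 0L || vstart + len - 1L > length(raw))
      stop("read_dicom_slice: truncated element in ", path)
    val <- raw[vstart:(vstart + len - 1L)]
    fields[[dicom_tag(group, elem)]] <- list(vr = vr, value = val)
    pos <- vstart + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  need <- function(tag, what) {
    f <- fields[[tag]]
    if (is.null(f)) stop("read_dicom_slice: missing ", what, " in ", path)
    f
  }
  u16 <- function(f) readBin(f$value, "integer", size = 2, signed = FALSE,
                             endian = "little")
  str1 <- function(f) trimws(rawToChar(f$value))
  rows <- u16(need(dicom_tag(0x0028, 0x0010), "Rows"))
  cols <- u16(need(dicom_tag(0x0028, 0x0011), "Columns"))
  bits <- u16(need(dicom_tag(0x0028, 0x0100), "BitsAllocated"))
  if (!bits %in% c(8L, 16L))
    stop("read_dicom_slice: unsupported BitsAllocated ", bits)
  px <- need(dicom_tag(0x7FE0, 0x0010), "PixelData")
  n <- rows * cols
  vals <- if (bits == 16L)
    readBin(px$value, "integer", n = n, size = 2, signed = FALSE,
            endian = "little")
  else as.integer(px$value[seq_len(n)])
  loc_f <- fields[[dicom_tag(0x0020, 0x1041)]]
  ins_f <- fields[[dicom_tag(0x0020, 0x0013)]]
  sp_f <- fields[[dicom_tag(0x0028, 0x0030)]]
  sp <- if (!is.null(sp_f)) as.numeric(strsplit(str1(sp_f), "\\\\")[[1]]) else NULL
  list(pixels = matrix(as.double(vals), rows, cols, byrow = TRUE),
       slice_location = if (!is.null(loc_f)) as.numeric(str1(loc_f)) else NA_real_,
       instance_number = if (!is.null(ins_f)) as.numeric(str1(ins_f)) else NA_real_,
       pixel_spacing = sp)
}

#' Write a synthetic single-frame DICOM slice (testing aid)
#'
#' Emits a minimal explicit-VR little-endian part-10 file carrying a
#' 16-bit grayscale frame plus SliceLocation/InstanceNumber/PixelSpacing.
#' This writer exists to build synthetic series for tests and examples;
#' it is not a general DICOM export.
#'
#' @param pixels numeric matrix; values are clipped to `[0, 65535]` and
#'   rounded to integers.
#' @param path output file path.
#' @param slice_location,instance_number ordering metadata.
#' @param pixel_spacing numeric `(row_mm, col_mm)`.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(pixels, path, slice_location = 0,
                              instance_number = 1, pixel_spacing = c(1, 1)) {
  pixels <- as.matrix(pixels)
  vals <- as.integer(round(pmin(pmax(pixels, 0), 65535)))
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  pad_even <- function(s) if (nchar(s) %% 2L == 1L) paste0(s, " ") else s
  short_el <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), charToRaw(vr), u16(length(value_raw)), value_raw)
  }
  long_el <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"), value_raw)
  }
  str_el <- function(group, elem, vr, s) short_el(group, elem, vr,
                                                  charToRaw(pad_even(s)))
  ts <- str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta_len <- short_el(0x0002, 0x0000, "UL",
                       writeBin(length(ts), raw(), size = 4, endian = "little"))
  pix_raw <- writeBin(as.integer(t(matrix(vals, nrow(pixels), ncol(pixels)))),
                      raw(), size = 2, endian = "little")
  body <- c(
    str_el(0x0020, 0x0013, "IS", format(instance_number)),
    str_el(0x0020, 0x1041, "DS", format(slice_location)),
    short_el(0x0028, 0x0010, "US", u16(nrow(pixels))),
    short_el(0x0028, 0x0011, "US", u16(ncol(pixels))),
    str_el(0x0028, 0x0030, "DS",
           paste(format(pixel_spacing[1]), format(pixel_spacing[2]), sep = "\\")),
    short_el(0x0028, 0x0100, "US", u16(16L)),
    short_el(0x0028, 0x0103, "US", u16(0L)),
    long_el(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, ts, body), con)
  invisible(path)
}

#' Dataset manifest
#'
#' A manifest maps image paths to an optional T stage in `{1,2,3,4}` and
#' a patient identifier used for grouped cross-validation splits.
#'
#' @param path character vector of image paths (must be unique).
#' @param label integer stages in `{1,2,3,4}` or `NA` for unlabeled rows.
#' @param patient_id character patient identifiers.
#' @return A `data.frame` of class `dataset_manifest` with columns
#'   `path`, `label`, `patient_id`.
#' @export
dataset_manifest <- function(path, label = NA_integer_, patient_id = "") {
  path <- as.character(path)
  n <- length(path)
  label <- suppressWarnings(as.integer(rep_len(label, n)))
  patient_id <- as.character(rep_len(patient_id, n))
  if (anyDuplicated(path)) stop("dataset_manifest: duplicate paths")
  bad <- !is.na(label) & !(label %in% 1:4)
  if (any(bad)) stop("dataset_manifest: labels must be in {1,2,3,4}; got ",
                     paste(unique(label[bad]), collapse = ", "))
  structure(data.frame(path = path, label = label, patient_id = patient_id,
                       stringsAsFactors = FALSE),
            class = c("dataset_manifest", "data.frame"))
}

#' Read / write a manifest CSV
#'
#' The CSV carries the header `path,label,patient_id`; blank labels mark
#' unlabeled images.  `read_manifest(write_manifest(m, f))` is the
#' identity on valid manifests.
#'
#' @param path CSV file path.
#' @return A [dataset_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("path", "label", "patient_id") %in% names(df)))
    stop("read_manifest: header must contain path,label,patient_id")
  lab <- suppressWarnings(as.integer(df$label))
  bad <- nzchar(trimws(df$label)) & is.na(lab)
  if (any(bad)) stop("read_manifest: non-numeric label: ",
                     paste(unique(df$label[bad]), collapse = ", "))
  dataset_manifest(df$path, lab, df$patient_id)
}

#' @param m a [dataset_manifest()].
#' @rdname read_manifest
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "dataset_manifest"))
  out <- data.frame(path = m$path,
                    label = ifelse(is.na(m$label), "", as.character(m$label)),
                    patient_id = m$patient_id)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
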