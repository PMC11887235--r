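#' Grayscale raster image
#'
#' The unit of filtering and training: a 2D grid of finite real
#' intensities with optional physical pixel spacing.  The coordinate
#' convention throughout the package is (row, col), 1-based, origin at
#' the top-left; crops are half-open in the sense that a crop of height
#' `h` starting at row `r` covers rows `r, ..., r + h - 1`.
#'
#' @param pixels numeric matrix of intensities (promoted to double).
#' @param spacing optional numeric `(row_mm, col_mm)`, both positive.
#' @param source_id character identifier carried through the pipeline.
#' @return An object of class `raster_image` with elements `pixels`,
#'   `spacing` and `source_id`.
#' @examples
#' img <- raster_image(matrix(runif(64), 8, 8), source_id = "a")
#' dim(img)
#' @export
raster_image <- function(pixels, spacing = NULL, source_id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) == 0L) stop("raster_image: empty pixel grid")
  if (!all(is.finite(pixels))) stop("raster_image: intensities must be finite")
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("raster_image: spacing must be two positive reals")
  }
  structure(list(pixels = pixels, spacing = spacing,
                 source_id = as.character(source_id)[1L]),
            class = "raster_image")
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %dx%d '%s' range [%.4g, %.4g]>\n",
              d[1], d[2], x$source_id, min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_raster <- function(x, source_id = "") {
  if (inherits(x, "raster_image")) x else raster_image(x, source_id = source_id)
}

#' 3D intensity volume
#'
#' Axis order is (slice, row, col); slices are the axial plane from which
#' 2D training images are extracted.
#'
#' @param voxels 3D numeric array indexed `[slice, row, col]`.
#' @param spacing optional positive numeric 3-tuple (slice, row, col), mm.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, spacing = NULL) {
  if (length(dim(voxels)) != 3L) stop("mri_volume: voxels must be a 3D array")
  if (dim(voxels)[1] < 1L) stop("mri_volume: at least one slice required")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels))) stop("mri_volume: voxels must be finite")
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("mri_volume: spacing must be three positive reals")
  }
  structure(list(voxels = voxels, spacing = spacing), class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mri_volume %d slices of %dx%d>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Extract 2D slices from a volume
#'
#' Cuts the volume along the axial (first) axis into one [raster_image()]
#' per slice.  With `normalize = "minmax"` each slice is mapped affinely
#' onto `[0, 1]`; a constant slice maps to all zeros.
#'
#' @param v an [mri_volume()].
#' @param plane slicing plane; only `"axial"` is supported.
#' @param normalize `"none"` or `"minmax"`.
#' @param id_prefix prefix for the generated `source_id`s.
#' @return List of [raster_image()] objects, one per slice.
#' @export
volume_to_slices <- function(v, plane = "axial",
                             normalize = c("none", "minmax"),
                             id_prefix = "slice") {
  stopifnot(inherits(v, "mri_volume"))
  plane <- match.arg(plane, "axial")
  normalize <- match.arg(normalize)
  sp <- if (!is.null(v$spacing)) v$spacing[2:3] else NULL
  lapply(seq_len(dim(v$voxels)[1]), function(s) {
    m <- v$voxels[s, , ]
    if (normalize == "minmax") m <- minmax_scale(m)
    raster_image(m, spacing = sp, source_id = sprintf("%s_%03d", id_prefix, s))
  })
}

#' Min-max rescaling with a constant-input rule
#'
#' Maps a matrix affinely onto `[0, 1]`; a constant matrix maps to zeros.
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
minmax_scale <- function(m) {
  r <- range(m)
  if (r[2] - r[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - r[1]) / (r[2] - r[1])
}

#' Read a grayscale raster from a PNG file
#'
#' 8- and 16-bit grayscale PNGs are promoted to doubles in `[0, 1]`;
#' multi-channel PNGs are collapsed by averaging the color channels.
#'
#' @param path PNG file path.
#' @param source_id identifier; defaults to the file name.
#' @return A [raster_image()].
#' @export
read_raster <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("read_raster: no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE],
                                       c(1, 2), mean)
  raster_image(a, source_id = source_id)
}

#' Write a raster as a grayscale PNG
#'
#' Intensities are clipped to `[0, 1]` before writing; pass a min-max
#' scaled image (see [minmax_scale()]) to preserve relative contrast.
#'
#' @param img a [raster_image()] (or matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  img <- as_raster(img)
  m <- pmin(pmax(img$pixels, 0), 1)
  png::writePNG(m, path)
  invisible(path)
}
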