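# Bilinear sampling at fractional (row, col) coordinates with symmetric
# reflection at the borders; the shared interpolation primitive behind
# rotation.
bilinear_sample <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  reflect <- function(x, n) {
    # map onto [1, n] by mirroring (border included)
    if (n == 1L) return(rep(1, length(x)))
    p <- 2 * (n - 1)
    x <- (x - 1) %% p
    ifelse(x > (n - 1), p - x, x) + 1
  }
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  i0 <- reflect(r0, H); i1 <- reflect(r0 + 1, H)
  j0 <- reflect(c0, W); j1 <- reflect(c0 + 1, W)
  m[cbind(i0, j0)] * (1 - fr) * (1 - fc) +
    m[cbind(i1, j0)] * fr * (1 - fc) +
    m[cbind(i0, j1)] * (1 - fr) * fc +
    m[cbind(i1, j1)] * fr * fc
}

#' Bilinear image resize
#'
#' Thin wrapper over `EBImage::resize()` returning a plain matrix in the
#' package's (row, col) convention.
#'
#' @param m numeric matrix.
#' @param h,w output height (rows) and width (cols).
#' @return `h` x `w` numeric matrix.
#' @export
resize_bilinear <- function(m, h, w) {
  m <- if (inherits(m, "raster_image")) m$pixels else as.matrix(m)
  if (nrow(m) == h && ncol(m) == w) return(m)
  # EBImage's first dimension is its "width"; our rows map onto it.
  out <- EBImage::resize(m, w = h, h = w)
  matrix(as.numeric(out), h, w)
}

#' Rotate an image about its center
#'
#' Multiples of 90 degrees are exact pixel permutations (lossless);
#' other angles use bilinear interpolation with symmetric reflection
#' outside the support.  Output shape equals input shape.
#'
#' @param img a [raster_image()] or matrix.
#' @param degrees counter-clockwise rotation angle.
#' @return Matrix of the rotated pixels.
#' @export
rotate_raster <- function(img, degrees) {
  m <- if (inherits(img, "raster_image")) img$pixels else as.matrix(img)
  deg <- degrees %% 360
  if (deg == 0) return(m)
  if (deg %in% c(90, 180, 270)) {
    rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]  # one CCW quarter turn
    for (i in seq_len(deg / 90)) m <- rot90(m)
    return(m)
  }
  H <- nrow(m); W <- ncol(m)
  th <- deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  i <- rep(seq_len(H), times = W); j <- rep(seq_len(W), each = H)
  # inverse map: output pixel pulls from the source rotated by -theta
  dy <- i - cy; dx <- j - cx
  sy <- cy + cos(th) * dy - sin(th) * dx
  sx <- cx + sin(th) * dy + cos(th) * dx
  matrix(bilinear_sample(m, sy, sx), H, W)
}

#' Augmentation specification
#'
#' Describes the stochastic view pipeline used at training time: rotate,
#' (random or central) crop with optional scale jitter and resize back,
#' then flips.  The whole stream is a pure function of
#' `(seed, draw_index)`, so augmented epochs are reproducible.
#'
#' @param out_size integer `(h, w)` of every augmented view.
#' @param allow_flip_h,allow_flip_v allow horizontal / vertical flips
#'   (each applied with probability 1/2 when allowed).
#' @param rotation_degrees numeric vector of candidate angles in
#'   `[0, 360)`; one is drawn uniformly per view.  The default right
#'   angles are lossless.
#' @param crop `"random"` or `"central"`.
#' @param scale_range crop side as a fraction of `out_size`; the crop is
#'   resized back to `out_size`.  `c(1, 1)` disables scale jitter.
#' @param seed base RNG seed for the augmentation stream.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(out_size = c(56L, 56L), allow_flip_h = TRUE,
                         allow_flip_v = FALSE,
                         rotation_degrees = c(0, 90, 180, 270),
                         crop = c("random", "central"),
                         scale_range = c(1, 1), seed = 0L) {
  crop <- match.arg(crop)
  out_size <- as.integer(out_size)
  if (length(out_size) != 2L || any(out_size <= 0L))
    stop("augment_spec: out_size must be two positive integers")
  rotation_degrees <- as.numeric(rotation_degrees) %% 360
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[1] > scale_range[2])
    stop("augment_spec: invalid scale_range")
  structure(list(out_size = out_size, allow_flip_h = allow_flip_h,
                 allow_flip_v = allow_flip_v,
                 rotation_degrees = rotation_degrees, crop = crop,
                 scale_range = scale_range, seed = as.integer(seed)),
            class = "augment_spec")
}

#' Central crop
#'
#' Crop of the given size centered on the image; odd margins are floored
#' on the top/left side (a `(4,4)` crop of a 9x9 image covers rows 3:6
#' in 1-based indexing, i.e. the half-open 0-based rows 2:6).
#'
#' @param img a [raster_image()] or matrix.
#' @param size integer `(h, w)` no larger than the image.
#' @return A [raster_image()] of the requested size.
#' @export
central_crop <- function(img, size) {
  img <- as_raster(img)
  size <- as.integer(size)
  d <- dim(img$pixels)
  if (any(size > d)) stop("central_crop: size exceeds image (", d[1], "x", d[2], ")")
  r0 <- (d[1] - size[1]) %/% 2L + 1L
  c0 <- (d[2] - size[2]) %/% 2L + 1L
  raster_image(img$pixels[r0:(r0 + size[1] - 1L), c0:(c0 + size[2] - 1L),
                          drop = FALSE],
               spacing = img$spacing, source_id = img$source_id)
}

#' Draw one augmented view of an image
#'
#' Applies rotate -> crop (+ resize when scale jitter is active) ->
#' flips.  The draw is deterministic given `(spec$seed, draw_index)`:
#' identical calls produce identical views, and distinct `draw_index`
#' values produce independent draws.
#'
#' @param img a [raster_image()] or matrix.
#' @param spec an [augment_spec()].
#' @param draw_index nonnegative integer indexing the draw.
#' @return A [raster_image()] of shape `spec$out_size`.
#' @export
augment_image <- function(img, spec, draw_index = 0L) {
  stopifnot(inherits(spec, "augment_spec"))
  img <- as_raster(img)
  seed_i <- (abs(spec$seed) * 1000003 + as.numeric(draw_index)) %% 2147483647
  withr::with_seed(as.integer(seed_i), {
    m <- img$pixels
    ang <- if (length(spec$rotation_degrees) > 1L)
      sample(spec$rotation_degrees, 1L) else spec$rotation_degrees
    if (length(ang) && ang != 0) m <- rotate_raster(m, ang)
    scale <- runif(1, spec$scale_range[1], spec$scale_range[2])
    cs <- pmax(1L, as.integer(round(spec$out_size * scale)))
    d <- dim(m)
    if (any(cs > d)) stop("augment_image: crop larger than image")
    if (spec$crop == "random") {
      r0 <- sample.int(d[1] - cs[1] + 1L, 1L)
      c0 <- sample.int(d[2] - cs[2] + 1L, 1L)
      m <- m[r0:(r0 + cs[1] - 1L), c0:(c0 + cs[2] - 1L), drop = FALSE]
    } else {
      m <- central_crop(m, cs)$pixels
    }
    if (!all(dim(m) == spec$out_size))
      m <- resize_bilinear(m, spec$out_size[1], spec$out_size[2])
    if (spec$allow_flip_h && runif(1) < 0.5) m <- m[, ncol(m):1, drop = FALSE]
    if (spec$allow_flip_v && runif(1) < 0.5) m <- m[nrow(m):1, , drop = FALSE]
    raster_image(m, spacing = img$spacing, source_id = img$source_id)
  })
}
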