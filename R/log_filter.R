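#' Unnormalized Gaussian kernel on the integer lattice
#'
#' Taps are `exp(-(x^2 + y^2) / (2 sigma^2))` sampled on a square lattice
#' of side `2 * ceiling(3 * sigma) + 1`; the normalizing coefficient is
#' deliberately omitted, so the center tap equals 1.
#'
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @return Numeric matrix of taps.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("gaussian_kernel: sigma must be > 0")
  h <- ceiling(3 * sigma)
  x <- -h:h
  r2 <- outer(x^2, x^2, "+")
  exp(-r2 / (2 * sigma^2))
}

#' Laplacian-of-Gaussian kernel
#'
#' The raw taps follow the analytic LoG,
#' `((x^2 + y^2 - 2 sigma^2) / sigma^4) * exp(-(x^2 + y^2) / (2 sigma^2))`,
#' on the same lattice as [gaussian_kernel()].  The continuous LoG
#' integrates to zero but its truncated sampling does not, so the mean
#' tap is subtracted from every tap ("zero-sum correction"): the
#' corrected kernel annihilates constant images exactly.
#'
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @return An object of class `log_kernel` with elements `taps` (zero-sum
#'   corrected), `raw` (analytic samples) and `sigma`.
#' @examples
#' k <- log_kernel(1)
#' sum(k$taps)            # exactly 0
#' k$raw[ceiling(nrow(k$raw) / 2), ceiling(ncol(k$raw) / 2)]  # -2
#' @export
log_kernel <- function(sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("log_kernel: sigma must be > 0")
  h <- ceiling(3 * sigma)
  x <- -h:h
  r2 <- outer(x^2, x^2, "+")
  raw <- ((r2 - 2 * sigma^2) / sigma^4) * exp(-r2 / (2 * sigma^2))
  taps <- raw - mean(raw)
  taps[h + 1L, h + 1L] <- taps[h + 1L, h + 1L] - sum(taps)  # kill fp residue
  structure(list(taps = taps, raw = raw, sigma = sigma), class = "log_kernel")
}

# 2D correlation with symmetric (reflect-including-border) padding.
# Implemented as a shift-and-accumulate over kernel taps: each tap is a
# vectorized add on the padded image, so cost is O(k^2 * H * W) with no
# interpreted inner loop.
conv2_reflect <- function(m, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  hh <- (kh - 1L) %/% 2L; hw <- (kw - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  if (H < kh || W < kw)
    stop("conv2_reflect: image smaller than kernel (", H, "x", W, " vs ",
         kh, "x", kw, ")")
  ri <- c(rev(seq_len(hh)), seq_len(H), seq(H, by = -1L, length.out = hh))
  ci <- c(rev(seq_len(hw)), seq_len(W), seq(W, by = -1L, length.out = hw))
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    w <- kern[i, j]
    if (w == 0) next
    out <- out + w * pad[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
  }
  out
}

#' Apply the LoG filter to an image
#'
#' Correlates the image with the zero-sum corrected LoG kernel; borders
#' are reflect-padded so the response has the shape of the input.  The
#' operation is linear and annihilates constant images exactly.
#'
#' @param img a [raster_image()] or matrix, at least as large as the kernel.
#' @param sigma kernel scale in pixels; default 1.6 is the staging
#'   preprocessing default.
#' @return An object of class `log_response` with elements `values`
#'   (signed matrix, same shape as the input) and `sigma`.
#' @export
apply_log <- function(img, sigma = 1.6) {
  img <- as_raster(img)
  k <- log_kernel(sigma)
  structure(list(values = conv2_reflect(img$pixels, k$taps), sigma = sigma),
            class = "log_response")
}

#' @export
print.log_response <- function(x, ...) {
  cat(sprintf("<log_response %dx%d sigma=%.3g range [%.4g, %.4g]>\n",
              nrow(x$values), ncol(x$values), x$sigma,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Detect strong zero-crossings of a LoG response
#'
#' A pixel is flagged when any 4-neighbor has strictly opposite sign and
#' the magnitude of the local sign change, `|resp(p) - resp(q)|`, exceeds
#' `strength_threshold`.  Threshold 0 keeps every sign change; weak
#' crossings (typically noise) are suppressed by raising it.
#'
#' @param resp a `log_response` (or numeric matrix).
#' @param strength_threshold nonnegative absolute-difference threshold.
#' @return Logical matrix of the response shape.
#' @export
detect_zero_crossings <- function(resp, strength_threshold = 0) {
  v <- if (inherits(resp, "log_response")) resp$values else as.matrix(resp)
  if (!is.finite(strength_threshold) || strength_threshold < 0)
    stop("detect_zero_crossings: threshold must be >= 0")
  H <- nrow(v); W <- ncol(v)
  mask <- matrix(FALSE, H, W)
  flag_pairs <- function(a, b) (a * b < 0) & (abs(a - b) > strength_threshold)
  if (H > 1) {
    f <- flag_pairs(v[-H, , drop = FALSE], v[-1, , drop = FALSE])
    mask[-H, ] <- mask[-H, ] | f
    mask[-1, ] <- mask[-1, ] | f
  }
  if (W > 1) {
    f <- flag_pairs(v[, -W, drop = FALSE], v[, -1, drop = FALSE])
    mask[, -W] <- mask[, -W] | f
    mask[, -1] <- mask[, -1] | f
  }
  mask
}

#' Suppress edge responses with the principal-curvature test
#'
#' Keypoints sitting on elongated edges have a large ratio of Hessian
#' trace squared to determinant.  A candidate at an interior pixel is
#' kept iff `det(H) > 0` and `tr(H)^2 / det(H) < (r + 1)^2 / r`; the
#' ratio is recorded as `edge_ratio` on survivors.  Candidates too close
#' to the border for central differences are skipped with a warning.
#'
#' @param resp a `log_response` (or numeric matrix).
#' @param candidates data frame with integer columns `row`, `col`
#'   (additional columns such as `level`, `score` pass through).
#' @param r curvature-ratio threshold, `> 1`; default 10.
#' @return The surviving rows of `candidates` with `edge_ratio` added.
#' @export
edge_response_filter <- function(resp, candidates, r = 10) {
  v <- if (inherits(resp, "log_response")) resp$values else as.matrix(resp)
  if (!is.finite(r) || r <= 1) stop("edge_response_filter: r must be > 1")
  stopifnot(is.data.frame(candidates), all(c("row", "col") %in% names(candidates)))
  H <- nrow(v); W <- ncol(v)
  i <- candidates$row; j <- candidates$col
  interior <- i >= 2 & i <= H - 1 & j >= 2 & j <= W - 1
  if (any(!interior)) {
    warning(sum(!interior), " candidate(s) outside the interior were skipped")
    candidates <- candidates[interior, , drop = FALSE]
    i <- candidates$row; j <- candidates$col
  }
  if (nrow(candidates) == 0L) {
    candidates$edge_ratio <- numeric(0)
    return(candidates)
  }
  at <- function(di, dj) v[cbind(i + di, j + dj)]
  dxx <- at(0, 1) - 2 * at(0, 0) + at(0, -1)
  dyy <- at(1, 0) - 2 * at(0, 0) + at(-1, 0)
  dxy <- (at(1, 1) - at(1, -1) - at(-1, 1) + at(-1, -1)) / 4
  det <- dxx * dyy - dxy^2
  tr <- dxx + dyy
  ratio <- ifelse(det > 0, tr^2 / det, Inf)
  keep <- det > 0 & ratio < (r + 1)^2 / r
  out <- candidates[keep, , drop = FALSE]
  out$edge_ratio <- ratio[keep]
  out
}

# Average 2x2 blocks; dimensions must be even.
downsample2 <- function(m) {
  H2 <- nrow(m) %/% 2L; W2 <- ncol(m) %/% 2L
  ri <- seq_len(H2) * 2L; ci <- seq_len(W2) * 2L
  (m[ri - 1L, ci - 1L, drop = FALSE] + m[ri, ci - 1L, drop = FALSE] +
     m[ri - 1L, ci, drop = FALSE] + m[ri, ci, drop = FALSE]) / 4
}

#' Four-level multi-scale image pyramid
#'
#' Levels are fixed at 640x480, 320x240, 160x120 and 80x60 pixels
#' (width x height).  Inputs of any other size are bilinearly resized to
#' 640x480 first; a 640x480 input passes through level 0 untouched.
#' Lower levels are built by successive 2x area (2x2 mean) downsampling,
#' which preserves constants exactly.
#'
#' @param img a [raster_image()] or matrix.
#' @return An object of class `image_pyramid`: a list `levels` of four
#'   [raster_image()]s with shapes (480,640), (240,320), (120,160), (60,80).
#' @export
build_pyramid <- function(img) {
  img <- as_raster(img)
  base <- img$pixels
  if (!identical(dim(base), c(480L, 640L)))
    base <- resize_bilinear(base, 480L, 640L)
  levels <- vector("list", 4L)
  levels[[1]] <- raster_image(base, source_id = paste0(img$source_id, "_L0"))
  for (l in 2:4) {
    base <- downsample2(base)
    levels[[l]] <- raster_image(base,
                                source_id = paste0(img$source_id, "_L", l - 1L))
  }
  structure(list(levels = levels), class = "image_pyramid")
}

#' @export
print.image_pyramid <- function(x, ...) {
  d <- vapply(x$levels, function(l) dim(l$pixels), integer(2))
  cat("<image_pyramid levels:",
      paste(sprintf("%dx%d", d[1, ], d[2, ]), collapse = ", "), ">\n")
  invisible(x)
}

#' Shi-Tomasi corner score at a pixel
#'
#' The minimum eigenvalue of the 2x2 structure tensor accumulated over a
#' square window of central-difference gradients.  Constant patches score
#' 0; pure 1D gradients score ~0 (rank-1 tensor); corner-like patches
#' score strictly positive.
#'
#' @param img a [raster_image()] or matrix.
#' @param row,col 1-based center pixel.
#' @param window odd window side; gradients require `window + 2` pixels
#'   of context, which must fit inside the image.
#' @return Nonnegative scalar score (up to numerical tolerance).
#' @export
shi_tomasi_score <- function(img, row, col, window = 5L) {
  img <- as_raster(img)
  m <- img$pixels
  if (window %% 2L != 1L || window < 3L)
    stop("shi_tomasi_score: window must be odd and >= 3")
  h <- (window - 1L) %/% 2L
  if (row - h < 2L || row + h > nrow(m) - 1L ||
      col - h < 2L || col + h > ncol(m) - 1L)
    stop("shi_tomasi_score: window (plus gradient margin) outside image")
  ri <- (row - h):(row + h); ci <- (col - h):(col + h)
  ix <- (m[ri, ci + 1L] - m[ri, ci - 1L]) / 2
  iy <- (m[ri + 1L, ci] - m[ri - 1L, ci]) / 2
  a <- sum(ix * ix); b <- sum(ix * iy); c <- sum(iy * iy)
  ((a + c) - sqrt((a - c)^2 + 4 * b^2)) / 2
}

# Dense Shi-Tomasi map via box-filtered gradient products; used by the
# keypoint detector so candidate scoring is O(H W) rather than per-point.
shi_tomasi_map <- function(m, window = 5L) {
  H <- nrow(m); W <- ncol(m)
  ix <- matrix(0, H, W); iy <- matrix(0, H, W)
  ix[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
  iy[2:(H - 1), ] <- (m[3:H, ] - m[1:(H - 2), ]) / 2
  box <- function(x, k) {
    h <- (k - 1L) %/% 2L
    out <- matrix(0, H, W)
    for (di in -h:h) for (dj in -h:h) {
      ri <- pmin(pmax(seq_len(H) + di, 1L), H)
      ci <- pmin(pmax(seq_len(W) + dj, 1L), W)
      out <- out + x[ri, ci]
    }
    out
  }
  a <- box(ix * ix, window); b <- box(ix * iy, window); c <- box(iy * iy, window)
  ((a + c) - sqrt((a - c)^2 + 4 * b^2)) / 2
}

#' Detect scale-stable keypoints on a pyramid level
#'
#' Convenience detector used by the command-line tool: strong
#' zero-crossings of the LoG response are scored with the Shi-Tomasi
#' map, thresholded at a fraction of the level's maximum score, and
#' surviving candidates are passed through the principal-curvature edge
#' test.
#'
#' @param img a [raster_image()] or matrix (one pyramid level).
#' @param sigma LoG scale.
#' @param level level index recorded on the keypoints.
#' @param window Shi-Tomasi window (odd).
#' @param score_frac keep candidates scoring above `score_frac * max score`.
#' @param zc_frac zero-crossing strength threshold as a fraction of
#'   `max |response|`.
#' @param r principal-curvature ratio threshold.
#' @return Data frame with columns `row`, `col`, `level`, `score`,
#'   `edge_ratio`.
#' @export
detect_keypoints <- function(img, sigma = 1.6, level = 0L, window = 5L,
                             score_frac = 0.01, zc_frac = 0.05, r = 10) {
  img <- as_raster(img)
  resp <- apply_log(img, sigma)
  thr <- zc_frac * max(abs(resp$values))
  mask <- detect_zero_crossings(resp, thr)
  st <- shi_tomasi_map(img$pixels, window)
  h <- (window - 1L) %/% 2L + 1L
  mask[c(seq_len(h), nrow(mask) - seq_len(h) + 1L), ] <- FALSE
  mask[, c(seq_len(h), ncol(mask) - seq_len(h) + 1L)] <- FALSE
  idx <- which(mask & st > score_frac * max(st), arr.ind = TRUE)
  cand <- data.frame(row = idx[, 1], col = idx[, 2], level = level,
                     score = st[idx])
  edge_response_filter(resp, cand, r = r)
}
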