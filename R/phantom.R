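#' Specification of the synthetic staged-phantom set
#'
#' The generator emulates the statistical structure the staging pipeline
#' relies on: each image is a ring ("bowel wall") whose relative wall
#' thickness and outward boundary irregularity both increase
#' monotonically with stage, mimicking the deepening wall invasion from
#' T1 to T4.  Images get angular wall texture, i.i.d. Gaussian pixel
#' noise, a random rotation (drawn as a phase of the angular structure)
#' and +/-10% scale jitter.  Default class proportions are 18/27/35/20%.
#'
#' @param n number of images, `>= 4`.
#' @param proportions four nonnegative class fractions summing to 1.
#' @param size image `(h, w)`; default `(64, 64)`.
#' @param noise_sigma Gaussian pixel-noise standard deviation (intensity
#'   units; wall/lumen contrast is about 0.65).
#' @param texture_contrast amplitude of the angular wall texture, `> 0`.
#' @param seed RNG seed; outputs are reproducible from the seed alone.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n, proportions = c(0.18, 0.27, 0.35, 0.20),
                         size = c(64L, 64L), noise_sigma = 0.05,
                         texture_contrast = 0.3, seed = 0L) {
  n <- as.integer(n)
  if (n < 4L) stop("phantom_spec: n must be >= 4")
  proportions <- as.numeric(proportions)
  if (length(proportions) != 4L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-9)
    stop("phantom_spec: proportions must be 4 nonnegative reals summing to 1")
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L))
    stop("phantom_spec: size must be two integers >= 16")
  if (noise_sigma < 0) stop("phantom_spec: noise_sigma must be >= 0")
  if (texture_contrast <= 0) stop("phantom_spec: texture_contrast must be > 0")
  structure(list(n = n, proportions = proportions, size = size,
                 noise_sigma = noise_sigma,
                 texture_contrast = texture_contrast, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Stage-dependent generative parameters: wall thickness as a fraction of
# the outer radius, and relative amplitude of the outward boundary
# irregularity.  Both strictly increase with stage.
.phantom_thickness_frac <- c(0.20, 0.35, 0.52, 0.72)
.phantom_irregularity <- c(0.02, 0.05, 0.09, 0.14)

# Largest-remainder apportionment of n into the 4 class counts.
largest_remainder_counts <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# Render one noiseless ring phantom.
render_phantom <- function(size, stage, scale, phase, tex_phase,
                           texture_contrast) {
  H <- size[1]; W <- size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r0 <- 0.38 * min(H, W) * scale
  y <- rep(seq_len(H), times = W) - cy
  x <- rep(seq_len(W), each = H) - cx
  rr <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  r_out <- r0 * (1 + .phantom_irregularity[stage] * sin(3 * th + phase))
  r_in <- r_out * (1 - .phantom_thickness_frac[stage])
  wall <- rr <= r_out & rr >= r_in
  tex <- 0.75 + 0.5 * texture_contrast * sin(6 * th + tex_phase)
  img <- ifelse(wall, tex, ifelse(rr < r_in, 0.15, 0.05))
  matrix(img, H, W)
}

#' Generate labeled staged ring phantoms
#'
#' Class counts follow the spec proportions under largest-remainder
#' rounding, so small sets still honor them.  At `noise_sigma = 0` and a
#' fixed seed, regeneration is bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return List with `images` (list of [raster_image()]) and `labels`
#'   (integer stages in 1..4, shuffled order).
#' @export
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  counts <- largest_remainder_counts(spec$n, spec$proportions)
  withr::with_seed(spec$seed, {
    labels <- sample(rep.int(1:4, counts))
    images <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      st <- labels[i]
      scale <- runif(1, 0.9, 1.1)
      phase <- runif(1, 0, 2 * pi)
      tex_phase <- runif(1, 0, 2 * pi)
      m <- render_phantom(spec$size, st, scale, phase, tex_phase,
                          spec$texture_contrast)
      if (spec$noise_sigma > 0)
        m <- m + matrix(rnorm(length(m), sd = spec$noise_sigma),
                        nrow(m), ncol(m))
      images[[i]] <- raster_image(m, source_id = sprintf("phantom_%04d", i))
    }
    list(images = images, labels = labels)
  })
}

#' Radial-profile features of a ring phantom
#'
#' Scale-invariant summaries used as an oracle feature space: the mean
#' relative wall thickness (wall extent between the outer and inner
#' radial crossings, divided by the outer radius) and the angular
#' variability of the outer radius (irregularity).  Phantom classes are
#' linearly separable in this space at zero noise.
#'
#' @param img a [raster_image()] or matrix.
#' @param n_angles number of radial spokes.
#' @return Named numeric vector `(rel_thickness, irregularity)`.
#' @export
radial_profile_features <- function(img, n_angles = 72L) {
  m <- if (inherits(img, "raster_image")) img$pixels else as.matrix(img)
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rmax <- min(H, W) / 2 - 1
  radii <- seq(1, rmax, by = 0.5)
  angs <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  outer_r <- numeric(n_angles); inner_r <- numeric(n_angles)
  thr <- (max(m) + min(m)) / 2
  for (a in seq_len(n_angles)) {
    ys <- cy + radii * sin(angs[a]); xs <- cx + radii * cos(angs[a])
    prof <- bilinear_sample(m, ys, xs)
    on <- which(prof > thr)
    if (length(on) == 0L) { outer_r[a] <- NA; inner_r[a] <- NA; next }
    outer_r[a] <- radii[max(on)]
    inner_r[a] <- radii[min(on)]
  }
  ok <- is.finite(outer_r) & is.finite(inner_r)
  rel <- (outer_r[ok] - inner_r[ok]) / outer_r[ok]
  c(rel_thickness = mean(rel),
    irregularity = stats::sd(outer_r[ok]) / mean(outer_r[ok]))
}

#' Gaussian feature blobs for clustering tests
#'
#' `k` isotropic unit-variance Gaussian blobs in `d` dimensions whose
#' centers are pairwise `separation` apart (in within-cluster standard
#' deviations); a global shift makes all coordinates nonnegative so the
#' rows are valid un-normalized conditionals.
#'
#' @param n number of points (split as evenly as possible over blobs).
#' @param d dimension.
#' @param k number of blobs.
#' @param separation pairwise center distance in within-sd units;
#'   0 collapses all blobs onto one center (null case).
#' @param seed RNG seed.
#' @return List with `features` (a [feature_matrix()]) and `labels`.
#' @export
generate_feature_blobs <- function(n, d, k, separation, seed = 0L) {
  n <- as.integer(n); d <- as.integer(d); k <- as.integer(k)
  if (n < k) stop("generate_feature_blobs: n must be >= k")
  if (d < k) stop("generate_feature_blobs: d must be >= k for simplex centers")
  withr::with_seed(as.integer(seed), {
    centers <- matrix(0, k, d)
    for (j in seq_len(k)) centers[j, j] <- separation / sqrt(2)
    counts <- largest_remainder_counts(n, rep(1 / k, k))
    labels <- sample(rep.int(seq_len(k), counts))
    vals <- centers[labels, , drop = FALSE] +
      matrix(rnorm(n * d), n, d)
    vals <- vals - min(vals)
    list(features = feature_matrix(vals, sprintf("blob_%04d", seq_len(n))),
         labels = labels)
  })
}
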