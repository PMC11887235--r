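# Fixture builders shared across the suite.  Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# Vertical step edge: low plateau left of column `edge_col`, high right.
step_image <- function(n = 64L, edge_col = n %/% 2L, lo = 0, hi = 1) {
  m <- matrix(lo, n, n)
  m[, (edge_col + 1L):n] <- hi
  m
}

# Unit checkerboard with cells of side `cell`.
checkerboard <- function(n = 11L, cell = 1L) {
  i <- (seq_len(n) - 1L) %/% cell
  outer(i, i, function(a, b) as.numeric((a + b) %% 2L == 0L))
}

# Filled disk of radius R centered in an n x n image.
disk_image <- function(n = 256L, R = 80) {
  c0 <- (n + 1) / 2
  d2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")
  (d2 <= R^2) * 1.0
}

# Quadratic patch with Hessian diag(2*a, 2*b) at the center; central
# differences recover the Hessian exactly on quadratics.
quadratic_patch <- function(n = 9L, a = 1, b = 1) {
  c0 <- (n + 1) / 2
  x <- seq_len(n) - c0
  outer(x, x, function(yy, xx) a * xx^2 + b * yy^2)
}

# Four visually distinct, trivially separable texture classes.  Copies of
# one class are exact duplicates (the noise seed depends on the class
# only), so co-clustering them is a hard requirement, not a statistical
# hope.
texture_image <- function(class, n = 28L) {
  base <- switch(class,
    matrix(rep(seq(0, 1, length.out = n), n), n, n),              # h-ramp
    matrix(rep(seq(0, 1, length.out = n), each = n), n, n),       # v-ramp
    checkerboard(n, cell = 4L),                                   # coarse check
    0.5 + 0.5 * sin(outer(seq_len(n), seq_len(n), "+") * pi / 3)) # diagonal wave
  withr::with_seed(class * 100L,
                   base + matrix(rnorm(n * n, sd = 0.02), n, n))
}

texture_set <- function(n_per_class = 4L, n = 28L) {
  images <- list(); labels <- integer(0)
  for (cl in 1:4) for (j in seq_len(n_per_class)) {
    images[[length(images) + 1L]] <-
      raster_image(texture_image(cl, n),
                   source_id = sprintf("tex_%d_%d", cl, j))
    labels <- c(labels, cl)
  }
  list(images = images, labels = labels)
}

# Enumerate all k^N assignments and return their from-scratch objectives.
enumerate_objectives <- function(joint, N, k, lam = 100) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), N)))
  apply(grid, 1, function(a)
    logstage:::cluster_state_from_assignment(as.integer(a), joint, k, lam)$objective)
}

# Brute-force pairwise AUC (normalized Mann-Whitney U).
pairwise_auc <- function(truth, scores) {
  pos <- scores[as.logical(truth)]; neg <- scores[!as.logical(truth)]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

write_test_nifti <- function(a, path = tempfile(fileext = ".nii.gz")) {
  RNifti::writeNifti(RNifti::asNifti(a), path)
  path
}

# A 3-slice synthetic DICOM series written in shuffled file order with
# out-of-order slice locations.
write_test_dicom_series <- function(dir = tempfile()) {
  dir.create(dir)
  set.seed(77)
  slices <- lapply(1:3, function(i) matrix(sample.int(4000, 48, TRUE), 6, 8))
  loc <- c(12.5, 2.5, 7.5)        # sorted order: slice 2, 3, 1
  for (i in 1:3)
    write_dicom_slice(slices[[i]], file.path(dir, sprintf("im%d.dcm", i)),
                      slice_location = loc[i], instance_number = i,
                      pixel_spacing = c(0.8, 0.8))
  list(dir = dir, slices = slices, loc = loc)
}
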