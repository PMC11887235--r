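test_that("Gaussian kernel samples the unnormalized density", {
  g <- gaussian_kernel(1)
  expect_equal(dim(g), c(7L, 7L))        # 2*ceil(3*sigma)+1
  c0 <- 4L
  expect_identical(g[c0, c0], 1.0)
  expect_equal(g[c0 + 1L, c0], exp(-0.5))
  expect_equal(g, t(g))
  expect_equal(g, g[7:1, 7:1])
  expect_error(gaussian_kernel(0), "sigma")
})

test_that("LoG kernel matches the analytic form and is zero-sum corrected", {
  k1 <- log_kernel(1)
  c0 <- 4L
  expect_equal(k1$raw[c0, c0], -2)
  expect_equal(k1$raw[c0 + 1L, c0 + 1L], 0)   # x^2 + y^2 = 2 sigma^2
  k2 <- log_kernel(2)
  c2 <- (nrow(k2$raw) + 1L) %/% 2L
  expect_equal(k2$raw[c2, c2], -0.5)
  expect_equal(sum(k1$taps), 0)
  expect_equal(sum(k2$taps), 0)
  expect_equal(k1$taps, t(k1$taps))
})

test_that("LoG filtering annihilates constants and is linear", {
  expect_true(all(abs(apply_log(matrix(3.7, 20, 20), 1)$values) < 1e-12))
  set.seed(5)
  a <- matrix(runif(32 * 32), 32, 32)
  expect_equal(apply_log(4 * a - 2, 1.4)$values,
               4 * apply_log(a, 1.4)$values, tolerance = 1e-12)
  expect_error(apply_log(matrix(0, 4, 4), 2), "smaller than")
})

test_that("filtering commutes with quarter turns", {
  rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]
  set.seed(8)
  a <- matrix(runif(40 * 40), 40, 40)
  expect_equal(apply_log(rot90(a), 1.6)$values,
               rot90(apply_log(a, 1.6)$values), tolerance = 1e-12)
})

test_that("step edges produce a thin zero-crossing line; thresholds prune it", {
  resp <- apply_log(step_image(64), 1.5)
  # sign flips across the edge on every row
  expect_true(all(resp$values[, 31] * resp$values[, 34] < 0))
  mask <- detect_zero_crossings(resp, 0)
  per_row <- rowSums(mask[5:60, ])
  expect_true(all(per_row >= 1 & per_row <= 4))
  expect_true(all(colSums(mask[, c(1:29, 41:64)]) == 0))
  expect_equal(sum(detect_zero_crossings(resp, 10 * max(abs(resp$values)))), 0L)
  expect_equal(sum(detect_zero_crossings(matrix(0, 8, 8), 0)), 0L)
})

test_that("zero-crossing locus of a large disk stays near the true circle", {
  R <- 80
  resp <- apply_log(disk_image(256, R), 2)
  mask <- detect_zero_crossings(resp, 0.2 * max(abs(resp$values)))
  idx <- which(mask, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - 128.5)^2 + (idx[, 2] - 128.5)^2)
  r <- r[abs(r - R) < 10]                 # the edge band, not far-field noise
  expect_gt(length(r), 100)
  expect_lt(mean(abs(r - R)), 1.5)
})

test_that("principal-curvature test keeps blobs and rejects ridges/saddles", {
  # isotropic: Hessian diag(2, 2); ratio 4 < (10+1)^2/10 = 12.1
  iso <- quadratic_patch(9, 1, 1)
  kept <- edge_response_filter(iso, data.frame(row = 5L, col = 5L), r = 10)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$edge_ratio, 4)
  # 20:1 eigenvalues: 21^2/20 = 22.05 > 12.1
  ridge <- quadratic_patch(9, 10, 0.5)
  expect_equal(nrow(edge_response_filter(ridge,
                                         data.frame(row = 5L, col = 5L),
                                         r = 10)), 0L)
  # saddle: det <= 0
  saddle <- quadratic_patch(9, 1, -1)
  expect_equal(nrow(edge_response_filter(saddle,
                                         data.frame(row = 5L, col = 5L),
                                         r = 10)), 0L)
  expect_warning(
    edge_response_filter(iso, data.frame(row = 1L, col = 5L), r = 10),
    "skipped")
})

test_that("pyramid has the four fixed level shapes for any input", {
  for (input in list(matrix(runif(480 * 640), 480, 640),
                     matrix(runif(100 * 70), 100, 70))) {
    p <- build_pyramid(input)
    shapes <- vapply(p$levels, function(l) dim(l$pixels), integer(2))
    expect_equal(shapes, cbind(c(480L, 640L), c(240L, 320L),
                               c(120L, 160L), c(60L, 80L)))
  }
  # native-resolution input passes through level 0 untouched
  native <- matrix(runif(480 * 640), 480, 640)
  expect_identical(build_pyramid(native)$levels[[1]]$pixels, native)
  # 2x2 averaging preserves constants at every level
  cp <- build_pyramid(matrix(2.5, 480, 640))
  for (l in cp$levels) expect_true(all(l$pixels == 2.5))
})

test_that("Shi-Tomasi score separates flats, edges and corners", {
  expect_equal(shi_tomasi_score(matrix(1, 11, 11), 6, 6, 5), 0)
  grad <- matrix(rep(seq_len(11), each = 11), 11, 11)   # pure vertical gradient
  expect_lt(abs(shi_tomasi_score(grad, 6, 6, 5)), 1e-9)
  corner <- checkerboard(11, cell = 3L)   # cell 1 has zero central differences
  expect_gt(shi_tomasi_score(corner, 6, 6, 5), 0.1)
  expect_error(shi_tomasi_score(matrix(1, 11, 11), 2, 6, 5), "outside")
})
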