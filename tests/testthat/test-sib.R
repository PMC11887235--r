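test_that("features_to_joint builds a valid joint with uniform p(x)", {
  j <- features_to_joint(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(sum(j$p_xy), 1, tolerance = 1e-12)
  expect_equal(j$p_x, c(0.5, 0.5))
  expect_equal(j$p_xy[1, 1], 0.5, tolerance = 1e-6)
  expect_lt(j$p_xy[1, 2], 1e-7)
  expect_equal(rowSums(j$p_y_given_x), c(1, 1), tolerance = 1e-12)
  # negatives clipped: the cell contributes ~0 mass
  jn <- features_to_joint(matrix(c(-5, 1, 1, 1), 2, 2, byrow = TRUE))
  expect_lt(jn$p_xy[1, 1], 1e-7)
  expect_error(features_to_joint(matrix(c(1, Inf, 1, 1), 2, 2)), "finite")
})

test_that("mutual information closed forms", {
  expect_equal(mutual_information(outer(c(0.3, 0.7), c(0.2, 0.8))), 0)
  expect_equal(mutual_information(diag(c(0.5, 0.5))), log(2))
  expect_equal(mutual_information(matrix(0.25, 2, 2)), 0)
  expect_error(mutual_information(matrix(0.3, 2, 2)), "mass")
})

test_that("Jensen-Shannon divergence closed forms and bounds", {
  expect_equal(js_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  hw <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(js_divergence(c(1, 0), c(0, 1), c(0.9, 0.1)), hw)
  expect_error(js_divergence(c(1, 0), c(0.5, 0.25, 0.25)), "length")
  set.seed(10)
  for (i in 1:20) {
    p <- runif(6); p <- p / sum(p)
    q <- runif(6); q <- q / sum(q)
    w1 <- runif(1, 0.05, 0.95); w <- c(w1, 1 - w1)
    js <- js_divergence(p, q, w)
    expect_gte(js, 0)
    expect_lte(js, -sum(w * log(w)) + 1e-12)
  }
})

test_that("merger cost equals the from-scratch objective difference", {
  set.seed(21)
  for (trial in 1:20) {
    N <- sample(4:10, 1); k <- sample(2:3, 1)
    joint <- features_to_joint(matrix(runif(N * 4), N, 4))
    a <- sample(rep_len(seq_len(k), N))
    x <- sample.int(N, 1)
    a_drawn <- a; a_drawn[x] <- NA
    st <- logstage:::cluster_state_from_assignment(a_drawn, joint, k, 100)
    for (t in seq_len(k)) {
      a_merged <- a_drawn; a_merged[x] <- t
      st_m <- logstage:::cluster_state_from_assignment(a_merged, joint, k, 100)
      expect_equal(merger_cost(st, joint, x, t),
                   st$objective - st_m$objective, tolerance = 1e-9)
    }
  }
  # identical conditionals cost nothing on the information term
  F <- matrix(rep(c(2, 1, 1, 0), 6), 6, 4, byrow = TRUE)
  joint <- features_to_joint(F)
  a <- c(1, 1, 2, 2, 2, NA)
  st <- logstage:::cluster_state_from_assignment(a, joint, 2L, 1e12)
  expect_equal(merger_cost(st, joint, 6L, 1L), 0, tolerance = 1e-12)
  expect_error(merger_cost(st, joint, 1L, 1L), "drawn")
})

test_that("sIB recovers duplicated groups exactly (verified exhaustively)", {
  F <- rbind(matrix(rep(c(5, 1, 0, 0), 5), 5, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 5), 5), 5, 4, byrow = TRUE))
  truth <- rep(1:2, each = 5)
  st <- sib_cluster(feature_matrix(F), sib_config(k = 2L, seed = 1L,
                                                  restarts = 3L))
  expect_equal(nmi(st$assignment, truth), 1)
  joint <- features_to_joint(F)
  objs <- enumerate_objectives(joint, 10L, 2L)
  expect_gte(st$objective, max(objs) - 1e-9)
})

test_that("N == k leaves every point its own cluster, preserving I(X;Y)", {
  set.seed(31)
  F <- matrix(runif(16), 4, 4)
  st <- sib_cluster(feature_matrix(F), sib_config(k = 4L, seed = 2L,
                                                  restarts = 2L))
  expect_equal(sort(st$assignment), 1:4)
  joint <- features_to_joint(F)
  i_xy <- mutual_information(joint$p_xy)
  expect_equal(st$objective, i_xy - log(4) / 100, tolerance = 1e-9)
})

test_that("objective trace is monotone and consistent with the final state", {
  g <- generate_feature_blobs(120, 8, 4, 4, seed = 5)
  st <- sib_cluster(g$features, sib_config(seed = 6L, restarts = 2L))
  expect_true(all(diff(st$trace) >= -1e-12))
  expect_equal(utils::tail(st$trace, 1), st$objective, tolerance = 1e-9)
  expect_true(st$converged)
  # data-processing inequality
  i_xy <- mutual_information(features_to_joint(g$features)$p_xy)
  p_ty <- st$p_y_given_t * st$p_t
  expect_lte(mutual_information(p_ty), i_xy + 1e-9)
})

test_that("one-pass cost scales sub-quadratically with N", {
  t_for <- function(n) {
    g <- generate_feature_blobs(n, 8, 4, 3, seed = 1)
    cfg <- sib_config(seed = 1L, restarts = 1L, max_passes = 1L)
    min(replicate(3, system.time(sib_cluster(g$features, cfg))["elapsed"]))
  }
  t1 <- t_for(100); t4 <- t_for(400)
  expect_lt(t4, max(0.25, 16 * t1))   # ~linear in N; guard against O(N^2)
})

test_that("NMI identities and the independence null", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(3, 3, 1, 1, 2, 2)), 1)   # permuted relabeling
  set.seed(12)
  x <- sample.int(4, 2000, TRUE); y <- sample.int(4, 2000, TRUE)
  expect_lt(nmi(x, y), 0.05)
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("k-means baseline clusters separable blobs", {
  g <- generate_feature_blobs(100, 8, 4, 10, seed = 3)
  km <- kmeans_baseline(g$features, k = 4, seed = 3)
  expect_gte(nmi(km$assignment, g$labels), 0.9)
})
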