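small_cfg <- function(...) {
  train_config(rounds = 1L, epochs_per_round = 2L, batch_size = 8L,
               seed = 5L,
               backbone = backbone_config("tiny_cnn", in_size = c(24L, 24L),
                                          feature_dim = 16L, seed = 5L),
               sib = sib_config(seed = 5L, restarts = 2L),
               augment = augment_spec(out_size = c(24L, 24L), seed = 5L),
               use_log = TRUE, ...)
}

test_that("pseudo-label rounds co-cluster duplicated images", {
  tx <- texture_set(n_per_class = 2L, n = 28L)
  cfg <- small_cfg()
  prep <- preprocess_images(tx$images, cfg)
  model <- build_model(cfg$backbone)
  pl <- suppressWarnings(pseudo_label_round(model, prep, cfg, round = 1L))
  expect_s3_class(pl, "pseudo_label_set")
  expect_length(pl$assignment, 8L)
  a <- pl$assignment
  for (cl in 1:4)   # the two copies of each texture share near-identical
    expect_equal(a[[paste0("tex_", cl, "_1")]], a[[paste0("tex_", cl, "_2")]])
  pl2 <- suppressWarnings(pseudo_label_round(model, prep, cfg, round = 1L))
  expect_identical(pl, pl2)
  expect_error(pseudo_label_round(model, prep[1:3], cfg), "at least")
})

test_that("learning rate zero leaves parameters unchanged except the head", {
  tx <- texture_set(n_per_class = 2L, n = 28L)
  cfg <- small_cfg(learning_rate = 0)
  cfg$augment <- augment_spec(out_size = c(24L, 24L), rotation_degrees = 0,
                              allow_flip_h = FALSE, crop = "central", seed = 5L)
  prep <- preprocess_images(tx$images, cfg)
  model <- build_model(cfg$backbone)
  labels <- structure(list(round = 1L,
                           assignment = stats::setNames(rep_len(1:4, 8),
                             vapply(prep, `[[`, "", "source_id")),
                           objective = 0),
                      class = "pseudo_label_set")
  tr <- train_round(model, prep, labels, cfg)
  conv_ids <- which(vapply(model$layers, function(l) !is.null(l$W), logical(1)))
  for (l in conv_ids)
    expect_identical(tr$model$layers[[l]]$W, model$layers[[l]]$W)
  expect_false(identical(tr$model$head$W, model$head$W))  # reinit rule
  expect_equal(tr$loss_trace[1], tr$loss_trace[2], tolerance = 1e-12)
})

test_that("training overfits trivially separable textures", {
  tx <- texture_set(n_per_class = 4L, n = 28L)
  cfg <- train_config(rounds = 1L, epochs_per_round = 20L, batch_size = 8L,
                      seed = 3L, learning_rate = 0.01,
                      backbone = backbone_config("tiny_cnn",
                                                 in_size = c(24L, 24L),
                                                 feature_dim = 16L, seed = 3L),
                      sib = sib_config(seed = 3L),
                      augment = augment_spec(out_size = c(24L, 24L),
                                             rotation_degrees = 0,
                                             allow_flip_h = FALSE, seed = 3L))
  prep <- preprocess_images(tx$images, cfg)
  model <- build_model(cfg$backbone)
  ids <- vapply(prep, `[[`, "", "source_id")
  labels <- structure(list(round = 1L,
                           assignment = stats::setNames(tx$labels, ids),
                           objective = 0),
                      class = "pseudo_label_set")
  tr <- train_round(model, prep, labels, cfg)
  expect_lt(utils::tail(tr$loss_trace, 1), tr$loss_trace[1])
  views <- logstage:::cluster_views(prep, cfg)
  pred <- vapply(views, function(v) which.max(classify(tr$model, v)),
                 integer(1))
  expect_gte(mean(pred == tx$labels), 0.95)
  bad <- structure(list(round = 1L,
                        assignment = labels$assignment[1:4], objective = 0),
                   class = "pseudo_label_set")
  expect_error(train_round(model, prep, bad, cfg), "cover")
})

test_that("fit is deterministic and records a complete history", {
  tx <- texture_set(n_per_class = 3L, n = 28L)
  cfg <- small_cfg()
  f1 <- suppressWarnings(fit(tx$images, cfg, truth = tx$labels))
  f2 <- suppressWarnings(fit(tx$images, cfg, truth = tx$labels))
  expect_identical(f1$pseudo_labels$assignment, f2$pseudo_labels$assignment)
  expect_identical(f1$model$head$W, f2$model$head$W)
  h <- f1$history[[1]]
  expect_named(h, c("round", "sib_objective", "loss_trace",
                    "nmi_prev_round", "nmi_truth"))
  expect_length(h$loss_trace, cfg$epochs_per_round)
  expect_false(is.na(h$nmi_truth))
  # every round yields exactly 4 non-empty pseudo-label groups
  expect_equal(sort(unique(as.integer(f1$pseudo_labels$assignment))), 1:4)
  expect_error(fit(tx$images[1:3], cfg), "at least 4")
})

test_that("identical inputs carry no class signal", {
  imgs <- lapply(1:8, function(i)
    raster_image(matrix(0.5, 24, 24), source_id = paste0("c", i)))
  cfg <- small_cfg()
  cfg$epochs_per_round <- 6L
  ft <- suppressWarnings(fit(imgs, cfg))
  # I(T;Y) vanishes; only the compression penalty -H(T)/lambda remains
  expect_lte(ft$history[[1]]$sib_objective, 1e-9)
  expect_gte(ft$history[[1]]$sib_objective, -log(4) / 100 - 1e-9)
  # the loss cannot beat the pseudo-label entropy (uniform-predictor floor)
  q <- tabulate(as.integer(ft$pseudo_labels$assignment), 4) / 8
  floor_h <- -sum(q[q > 0] * log(q[q > 0]))
  final_loss <- utils::tail(ft$history[[1]]$loss_trace, 1)
  expect_gte(final_loss, floor_h - 1e-6)
  expect_lt(final_loss, floor_h + 0.5)
})

test_that("Hungarian mapping maximizes the confusion trace", {
  clusters <- c(1, 1, 2, 2, 3, 3, 4, 4, 1)
  stages <- c(3, 3, 1, 1, 4, 4, 2, 2, 1)
  m <- stage_mapping(clusters, stages)
  expect_equal(m, c(3L, 1L, 4L, 2L))
  # trace under the mapping equals the number of consistent items
  expect_equal(sum(m[clusters] == stages), 8L)
  # permutation-invariance: relabeling clusters relabels the mapping
  perm <- c(2L, 3L, 4L, 1L)
  m2 <- stage_mapping(perm[clusters], stages)
  expect_equal(m2[perm], m)
})

test_that("predict_stage applies the cluster-to-stage permutation", {
  tx <- texture_set(n_per_class = 1L, n = 28L)
  cfg <- small_cfg()
  model <- build_model(cfg$backbone)
  p_id <- predict_stage(model, tx$images[[1]], cfg)
  expect_equal(sum(p_id$probs), 1, tolerance = 1e-6)
  expect_equal(p_id$stage, paste0("T", which.max(p_id$probs)))
  mapping <- c(4L, 3L, 2L, 1L)
  p_m <- predict_stage(model, tx$images[[1]], cfg, mapping = mapping)
  expect_equal(p_m$probs[mapping], p_id$probs)
  expect_error(predict_stage(model, tx$images[[1]], cfg, mapping = c(1L, 1L, 2L, 3L)),
               "permutation")
})
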