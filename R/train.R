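#' Training-loop configuration
#'
#' Settings of the alternating cluster/train loop: every round extracts
#' central-crop features, clusters them into four pseudo-label groups
#' and then runs a few epochs of minibatch SGD (momentum 0.9) on the
#' cross-entropy against those pseudo-labels, with train-time
#' augmentation.  Preprocessing applies the LoG filter (standardized
#' response) by default; `use_log = FALSE` and
#' `cluster_method = "kmeans"` are the two ablation axes.
#'
#' @param rounds cluster/train alternations.
#' @param epochs_per_round SGD epochs per round.
#' @param batch_size minibatch size.
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum coefficient.
#' @param seed master seed for model init, shuffling and augmentation.
#' @param backbone a [backbone_config()].
#' @param sib a [sib_config()].
#' @param augment an [augment_spec()]; its `out_size` must match the
#'   backbone `in_size`.
#' @param use_log apply LoG texture enhancement before training.
#' @param log_sigma LoG scale in pixels.
#' @param cluster_method `"sib"` (draw-and-merge) or `"kmeans"` baseline.
#' @return An object of class `train_config`.
#' @export
train_config <- function(rounds = 5L, epochs_per_round = 6L, batch_size = 32L,
                         learning_rate = 0.003, momentum = 0.9, seed = 0L,
                         backbone = backbone_config(seed = seed),
                         sib = sib_config(seed = seed),
                         augment = augment_spec(out_size = backbone$in_size,
                                                seed = seed),
                         use_log = TRUE, log_sigma = 1.6,
                         cluster_method = c("sib", "kmeans")) {
  cluster_method <- match.arg(cluster_method)
  if (rounds < 1L || epochs_per_round < 1L || batch_size < 1L)
    stop("train_config: counts must be positive")
  if (learning_rate < 0) stop("train_config: learning_rate must be >= 0")
  if (!all(augment$out_size == backbone$in_size))
    stop("train_config: augment out_size must equal backbone in_size")
  structure(list(rounds = as.integer(rounds),
                 epochs_per_round = as.integer(epochs_per_round),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed), backbone = backbone, sib = sib,
                 augment = augment, use_log = use_log, log_sigma = log_sigma,
                 cluster_method = cluster_method),
            class = "train_config")
}

#' Preprocess images for the staging pipeline
#'
#' With `use_log = TRUE` each image is replaced by its LoG response,
#' standardized to zero mean and unit standard deviation (constant
#' responses stay zero); otherwise intensities are min-max scaled.
#'
#' @param images list of [raster_image()]s or matrices.
#' @param cfg a [train_config()] (only `use_log` / `log_sigma` are used).
#' @return List of preprocessed [raster_image()]s.
#' @export
preprocess_images <- function(images, cfg) {
  lapply(images, function(im) {
    im <- as_raster(im)
    m <- if (isTRUE(cfg$use_log)) {
      v <- apply_log(im, cfg$log_sigma)$values
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    } else minmax_scale(im$pixels)
    raster_image(m, spacing = im$spacing, source_id = im$source_id)
  })
}

# Clean (deterministic) clustering view: central crop to the network input.
cluster_views <- function(images, cfg) {
  lapply(images, central_crop, size = cfg$backbone$in_size)
}

#' One pseudo-label generation round
#'
#' Extracts central-crop features and clusters them (k = 4, lambda = 100
#' by default) into a pseudo-label assignment.  A warning is raised when
#' any cluster holds more than 70% of the samples (trivial-solution
#' guard).  Deterministic given the configured seeds.
#'
#' @param model a [build_model()] result.
#' @param images preprocessed images (see [preprocess_images()]).
#' @param cfg a [train_config()].
#' @param round round counter recorded on the result.
#' @return An object of class `pseudo_label_set`: `round`, `assignment`
#'   (named integer vector, source_id -> cluster 1..k) and `objective`
#'   (the sIB objective; `NA` for the k-means baseline).
#' @export
pseudo_label_round <- function(model, images, cfg, round = 1L) {
  if (length(images) < cfg$sib$k)
    stop("pseudo_label_round: need at least ", cfg$sib$k, " images")
  feats <- extract_features(model, cluster_views(images, cfg))
  if (cfg$cluster_method == "sib") {
    st <- sib_cluster(feats, cfg$sib)
    assignment <- st$assignment
    objective <- st$objective
  } else {
    km <- kmeans_baseline(feats, k = cfg$sib$k, seed = cfg$sib$seed)
    assignment <- km$assignment
    objective <- NA_real_
  }
  share <- max(tabulate(assignment, cfg$sib$k)) / length(assignment)
  if (share > 0.7)
    warning(sprintf("pseudo_label_round: largest cluster holds %.0f%% of samples",
                    100 * share))
  names(assignment) <- feats$ids
  structure(list(round = as.integer(round), assignment = assignment,
                 objective = objective),
            class = "pseudo_label_set")
}

#' One supervised training round on pseudo-labels
#'
#' Reinitializes the classifier head (cluster identities are arbitrary
#' across rounds), then runs `epochs_per_round` epochs of minibatch SGD
#' with momentum on the negative log-softmax loss against the
#' pseudo-labels, drawing one augmented view per image per epoch.
#'
#' @param model a [build_model()] result.
#' @param images preprocessed images; every `source_id` must be covered
#'   by `labels`.
#' @param labels a `pseudo_label_set` (or named integer vector).
#' @param cfg a [train_config()].
#' @return List with the updated `model` and `loss_trace` (per-epoch
#'   mean loss).
#' @export
train_round <- function(model, images, labels, cfg) {
  lab <- if (inherits(labels, "pseudo_label_set")) labels$assignment else labels
  round_id <- if (inherits(labels, "pseudo_label_set")) labels$round else 0L
  ids <- vapply(images, function(im) as_raster(im)$source_id, character(1))
  if (!all(ids %in% names(lab)))
    stop("train_round: pseudo-labels do not cover all images")
  y <- as.integer(lab[ids])
  n <- length(images)
  model <- reinit_head(model, cfg$seed + 131L * round_id)
  vel <- init_velocity(model)
  k <- model$cfg$n_classes
  loss_trace <- numeric(cfg$epochs_per_round)
  for (ep in seq_len(cfg$epochs_per_round)) {
    ord <- withr::with_seed((cfg$seed + 7001L * round_id + ep) %% 2147483647L,
                            sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      views <- lapply(seq_along(idx), function(j) {
        di <- (round_id * 1e6 + ep * 1e4 + idx[j]) %% 2147483647
        augment_image(images[[idx[j]]], cfg$augment, draw_index = di)
      })
      x <- stack_images(views, model$cfg$in_size)
      fw <- model_forward(model, x, keep_caches = TRUE)
      probs <- softmax_cols(fw$logits)
      B <- length(idx)
      picked <- probs[cbind(y[idx], seq_len(B))]
      ep_loss <- ep_loss + sum(-log(pmax(picked, 1e-12)))
      if (cfg$learning_rate > 0) {
        dlogits <- probs
        dlogits[cbind(y[idx], seq_len(B))] <-
          dlogits[cbind(y[idx], seq_len(B))] - 1
        dlogits <- dlogits / B
        ghead <- list(W = dlogits %*% t(fw$features), b = rowSums(dlogits))
        gfeat <- t(model$head$W) %*% dlogits
        grads <- nn_backward(model$layers, fw$caches, gfeat)
        upd <- sgd_step(model, grads, ghead, vel,
                        cfg$learning_rate, cfg$momentum)
        model <- upd$model; vel <- upd$vel
      }
    }
    loss_trace[ep] <- ep_loss / n
  }
  list(model = model, loss_trace = loss_trace)
}

init_velocity <- function(model) {
  v <- lapply(model$layers, function(l)
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else NULL)
  list(layers = v, head = list(W = model$head$W * 0, b = model$head$b * 0))
}

sgd_step <- function(model, grads, ghead, vel, lr, mom) {
  for (l in seq_along(model$layers)) {
    if (is.null(grads[[l]])) next
    vel$layers[[l]]$W <- mom * vel$layers[[l]]$W - lr * grads[[l]]$W
    vel$layers[[l]]$b <- mom * vel$layers[[l]]$b - lr * grads[[l]]$b
    model$layers[[l]]$W <- model$layers[[l]]$W + vel$layers[[l]]$W
    model$layers[[l]]$b <- model$layers[[l]]$b + vel$layers[[l]]$b
  }
  vel$head$W <- mom * vel$head$W - lr * ghead$W
  vel$head$b <- mom * vel$head$b - lr * ghead$b
  model$head$W <- model$head$W + vel$head$W
  model$head$b <- model$head$b + vel$head$b
  list(model = model, vel = vel)
}

#' Fit the staging model by alternating clustering and training
#'
#' The label-generation loop: preprocess once, then for each round
#' cluster central-crop features into pseudo-labels and train on them.
#' The backbone persists across rounds; the head is reinitialized each
#' round.  Fully deterministic given the configured seeds.
#'
#' @param images list of [raster_image()]s (raw; preprocessing is applied
#'   internally).
#' @param cfg a [train_config()].
#' @param truth optional integer stages (1..4) used only to record
#'   `nmi_truth` in the history.
#' @return An object of class `stage_fit`: `model`, `pseudo_labels`
#'   (final round), `history` (per-round list with `round`,
#'   `sib_objective`, `loss_trace`, `nmi_prev_round`, `nmi_truth`), and
#'   `cfg`.
#' @export
fit <- function(images, cfg = train_config(), truth = NULL) {
  if (length(images) < 4L) stop("fit: need at least 4 images")
  if (!is.null(truth) && length(truth) != length(images))
    stop("fit: truth length must match images")
  prep <- preprocess_images(images, cfg)
  model <- build_model(cfg$backbone)
  history <- vector("list", cfg$rounds)
  prev <- NULL
  pl <- NULL
  for (r in seq_len(cfg$rounds)) {
    pl <- pseudo_label_round(model, prep, cfg, round = r)
    tr <- train_round(model, prep, pl, cfg)
    model <- tr$model
    history[[r]] <- list(
      round = r,
      sib_objective = pl$objective,
      loss_trace = tr$loss_trace,
      nmi_prev_round = if (!is.null(prev)) nmi(prev, pl$assignment) else NA_real_,
      nmi_truth = if (!is.null(truth)) nmi(truth, pl$assignment) else NA_real_)
    prev <- pl$assignment
  }
  structure(list(model = model, pseudo_labels = pl, history = history,
                 cfg = cfg),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  r <- length(x$history)
  cat(sprintf("<stage_fit rounds=%d final objective=%.4f nmi_prev=%.3f>\n",
              r, x$history[[r]]$sib_objective %||% NA,
              x$history[[r]]$nmi_prev_round))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Map anonymous clusters onto stages
#'
#' Clusters produced by unsupervised training are anonymous; given a
#' labeled subset, the permutation maximizing the trace of the
#' cluster-vs-stage confusion matrix (the Hungarian assignment, solved
#' exactly over all permutations for k <= 8) fixes the correspondence.
#'
#' @param clusters integer cluster indices (1..k).
#' @param stages integer true stages (1..k) for the same items.
#' @param k number of clusters/stages.
#' @return Integer vector `m` with `m[cluster] = stage`.
#' @export
stage_mapping <- function(clusters, stages, k = 4L) {
  if (length(clusters) != length(stages)) stop("stage_mapping: length mismatch")
  if (k > 8L) stop("stage_mapping: exhaustive assignment limited to k <= 8")
  conf <- matrix(0L, k, k)
  for (i in seq_along(clusters))
    conf[clusters[i], stages[i]] <- conf[clusters[i], stages[i]] + 1L
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(conf[cbind(seq_len(k), p)]),
                   numeric(1))
  perms[[which.max(scores)]]
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Predict the stage of a single image
#'
#' Preprocesses the image the same way as training (LoG + central crop),
#' runs the classifier and applies the cluster-to-stage mapping.
#'
#' @param model a trained model (from [fit()]'s `$model`) or a
#'   `stage_fit`.
#' @param img a [raster_image()] or matrix (raw, any size at least
#'   `in_size`).
#' @param cfg the [train_config()] used in training (taken from a
#'   `stage_fit` automatically).
#' @param mapping integer vector `m[cluster] = stage`, e.g. from
#'   [stage_mapping()]; `NULL` means identity (clusters reported as
#'   stages directly).
#' @return List with `stage` (`"T1"`..`"T4"`), `stage_index`, and
#'   `probs` (probability vector over stages, mapping applied).
#' @export
predict_stage <- function(model, img, cfg = NULL, mapping = NULL) {
  if (inherits(model, "stage_fit")) {
    cfg <- cfg %||% model$cfg
    model <- model$model
  }
  if (is.null(cfg)) stop("predict_stage: cfg required for preprocessing")
  prep <- preprocess_images(list(img), cfg)
  view <- cluster_views(prep, cfg)[[1]]
  probs <- classify(model, view)
  k <- length(probs)
  m <- if (is.null(mapping)) seq_len(k) else as.integer(mapping)
  if (length(m) != k || !setequal(m, seq_len(k)))
    stop("predict_stage: mapping must be a permutation of 1..", k)
  stage_probs <- numeric(k)
  stage_probs[m] <- probs
  si <- which.max(stage_probs)
  list(stage = paste0("T", si), stage_index = si, probs = stage_probs)
}
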