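#' Backbone configuration
#'
#' Desk-scale convolutional encoders sharing one interface: a forward
#' map from an `in_size` grayscale image to a `feature_dim` penultimate
#' feature vector plus `n_classes` logits from a linear head.
#' `tiny_cnn` (three conv blocks, ~25k parameters) is the default;
#' `vgg_small`, `resnet_small` and `alex_small` are reduced-width
#' variants of the classic architectures used for the
#' architecture-robustness axis — swapping them changes no interface.
#'
#' @param arch one of `"tiny_cnn"`, `"vgg_small"`, `"resnet_small"`,
#'   `"alex_small"`.
#' @param in_size input image `(h, w)`.
#' @param feature_dim penultimate feature dimension.
#' @param n_classes number of output classes (stages); default 4.
#' @param seed RNG seed for weight initialization.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(arch = c("tiny_cnn", "vgg_small", "resnet_small",
                                     "alex_small"),
                            in_size = c(56L, 56L), feature_dim = 64L,
                            n_classes = 4L, seed = 0L) {
  arch <- match.arg(arch)
  in_size <- as.integer(in_size)
  feature_dim <- as.integer(feature_dim)
  n_classes <- as.integer(n_classes)
  if (feature_dim <= 0L || n_classes <= 0L)
    stop("backbone_config: feature_dim and n_classes must be positive")
  structure(list(arch = arch, in_size = in_size, feature_dim = feature_dim,
                 n_classes = n_classes, seed = as.integer(seed)),
            class = "backbone_config")
}

conv_layer <- function(k, cin, cout, type = "conv") {
  fan_in <- k * k * cin
  list(type = type, k = k, cin = cin, cout = cout,
       W = he_init(fan_in, cout, fan_in), b = rep(0, cout))
}

arch_plan <- function(arch) {
  switch(arch,
    tiny_cnn = list(list("conv", 3L, 8L), "pool",
                    list("conv", 3L, 16L), "pool",
                    list("conv", 3L, 32L), "pool", "avgpool"),
    vgg_small = list(list("conv", 3L, 12L), list("conv", 3L, 12L), "pool",
                     list("conv", 3L, 24L), list("conv", 3L, 24L), "pool",
                     list("conv", 3L, 48L), list("conv", 3L, 48L), "pool",
                     "avgpool"),
    resnet_small = list(list("conv", 3L, 8L), "pool",
                        list("conv", 3L, 16L), list("resconv", 3L, 16L), "pool",
                        list("conv", 3L, 32L), list("resconv", 3L, 32L), "pool",
                        "avgpool"),
    alex_small = list(list("conv", 5L, 12L), "pool",
                      list("conv", 3L, 24L), "pool",
                      list("conv", 3L, 48L), "pool", "avgpool"),
    stop("build_model: unknown arch '", arch, "'")
  )
}

#' Build a backbone model
#'
#' Initialization is deterministic given `cfg$seed`: building twice with
#' the same config yields identical parameters.
#'
#' @param cfg a [backbone_config()].
#' @return An object of class `stage_model`: layer stack `layers`
#'   (ending in a `feature_dim` ReLU feature layer) and linear head
#'   `head` producing `n_classes` logits.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "backbone_config"))
  plan <- arch_plan(cfg$arch)
  withr::with_seed(cfg$seed, {
    layers <- list()
    H <- cfg$in_size[1]; W <- cfg$in_size[2]; C <- 1L
    for (step in plan) {
      if (identical(step, "pool")) {
        layers <- c(layers, list(list(type = "maxpool2")))
        H <- H %/% 2L; W <- W %/% 2L
      } else if (identical(step, "avgpool")) {
        layers <- c(layers, list(list(type = "avgpool2")))
        H <- H %/% 2L; W <- W %/% 2L
      } else {
        type <- step[[1]]; k <- step[[2]]; cout <- step[[3]]
        if (type == "resconv" && cout != C)
          stop("build_model: resconv requires matching channels")
        layers <- c(layers, list(conv_layer(k, C, cout, type)),
                    list(list(type = "relu")))
        C <- cout
      }
      if (H < 1L || W < 1L) stop("build_model: in_size too small for ", cfg$arch)
    }
    flat <- H * W * C
    layers <- c(layers, list(list(type = "flatten")),
                list(list(type = "fc", W = he_init(cfg$feature_dim, flat, flat),
                          b = rep(0, cfg$feature_dim))),
                list(list(type = "relu")))
    head <- list(W = he_init(cfg$n_classes, cfg$feature_dim, cfg$feature_dim),
                 b = rep(0, cfg$n_classes))
    structure(list(cfg = cfg, layers = layers, head = head),
              class = "stage_model")
  })
}

#' @export
print.stage_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L, numeric(1))) +
    length(x$head$W) + length(x$head$b)
  cat(sprintf("<stage_model %s in=%dx%d feature_dim=%d params=%d>\n",
              x$cfg$arch, x$cfg$in_size[1], x$cfg$in_size[2],
              x$cfg$feature_dim, as.integer(np)))
  invisible(x)
}

# Reinitialize the linear head (fresh seed); used at the start of every
# training round because cluster identities are arbitrary across rounds.
reinit_head <- function(model, seed) {
  withr::with_seed(as.integer(seed), {
    fd <- model$cfg$feature_dim
    model$head <- list(W = he_init(model$cfg$n_classes, fd, fd),
                       b = rep(0, model$cfg$n_classes))
  })
  model
}

# Stack a list of raster images (all of in_size) into an (H, W, 1, B) array.
stack_images <- function(images, in_size) {
  B <- length(images)
  x <- array(0, c(in_size[1], in_size[2], 1L, B))
  for (i in seq_len(B)) {
    m <- if (inherits(images[[i]], "raster_image")) images[[i]]$pixels
         else as.matrix(images[[i]])
    if (!all(dim(m) == in_size))
      stop("stack_images: image ", i, " is ", nrow(m), "x", ncol(m),
           ", expected ", in_size[1], "x", in_size[2])
    x[, , 1L, i] <- m
  }
  x
}

# Forward a batch: returns features (feature_dim x B), logits
# (n_classes x B) and caches when requested (training mode).
model_forward <- function(model, x, keep_caches = FALSE) {
  fw <- nn_forward(model$layers, x)
  feats <- fw$out
  logits <- model$head$W %*% feats + model$head$b
  list(features = feats, logits = logits,
       caches = if (keep_caches) fw$caches else NULL)
}

#' Extract per-image feature vectors
#'
#' Runs the backbone in evaluation mode (the forward pass is
#' deterministic; there are no stochastic layers) and returns the
#' penultimate-layer activation of every image.
#'
#' @param model a [build_model()] result.
#' @param images list of [raster_image()]s (or matrices) of `in_size`.
#' @param batch_size forward batch size.
#' @return A [feature_matrix()] with one row per image, `ids` taken from
#'   the images' `source_id`s.
#' @export
extract_features <- function(model, images, batch_size = 32L) {
  stopifnot(inherits(model, "stage_model"))
  n <- length(images)
  out <- matrix(0, n, model$cfg$feature_dim)
  ids <- vapply(seq_len(n), function(i) {
    im <- images[[i]]
    if (inherits(im, "raster_image") && nzchar(im$source_id)) im$source_id
    else sprintf("img_%04d", i)
  }, character(1))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_images(images[idx], model$cfg$in_size)
    out[idx, ] <- t(model_forward(model, x)$features)
  }
  feature_matrix(out, ids)
}

#' Classify one image into stage probabilities
#'
#' Softmax over the head logits: nonnegative probabilities summing to 1.
#'
#' @param model a [build_model()] result.
#' @param img a [raster_image()] or matrix of `in_size`.
#' @return Numeric probability vector of length `n_classes`.
#' @export
classify <- function(model, img) {
  x <- stack_images(list(img), model$cfg$in_size)
  as.numeric(softmax_cols(model_forward(model, x)$logits))
}
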