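# Minimal CNN engine: im2col + BLAS matrix multiplies on 4D arrays
# (H, W, C, B).  Index matrices for the im2col gather are cached per
# (shape, batch) because they are the only expensive thing to build.

.nn_cache <- new.env(parent = emptyenv())

conv_index <- function(H, W, C, k, B) {
  key <- paste(H, W, C, k, B, sep = "x")
  got <- .nn_cache[[key]]
  if (!is.null(got)) return(got)
  p <- (k - 1L) %/% 2L
  PH <- H + 2L * p; PW <- W + 2L * p
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  M0 <- matrix(0L, H * W, k * k * C)
  col <- 0L
  for (c in seq_len(C)) for (kj in 0:(k - 1L)) for (ki in 0:(k - 1L)) {
    col <- col + 1L
    M0[, col] <- (i + ki) + PH * ((j + kj - 1L) + PW * (c - 1L))
  }
  off <- (seq_len(B) - 1L) * (PH * PW * C)
  idx <- M0[rep(seq_len(H * W), B), , drop = FALSE] + rep(off, each = H * W)
  out <- list(idx = idx, p = p, PH = PH, PW = PW)
  .nn_cache[[key]] <- out
  out
}

conv_fwd <- function(x, W, b, k, cin, cout) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; B <- d[4]
  ci <- conv_index(H, Wd, cin, k, B)
  xpad <- array(0, c(ci$PH, ci$PW, cin, B))
  xpad[ci$p + seq_len(H), ci$p + seq_len(Wd), , ] <- x
  P <- matrix(xpad[ci$idx], nrow = H * Wd * B)
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = aperm(array(Y, c(H, Wd, B, cout)), c(1, 2, 4, 3)), P = P)
}

conv_bwd <- function(gy, P, W, k, cin, cout, need_gx = TRUE) {
  d <- dim(gy); H <- d[1]; Wd <- d[2]; B <- d[4]
  G <- matrix(aperm(gy, c(1, 2, 4, 3)), nrow = H * Wd * B)
  gW <- crossprod(P, G)
  gb <- colSums(G)
  gx <- NULL
  if (need_gx) {
    gP <- G %*% t(W)
    ci <- conv_index(H, Wd, cin, k, B)
    gpad <- array(0, c(ci$PH, ci$PW, cin, B))
    col <- 0L
    for (c in seq_len(cin)) for (kj in 0:(k - 1L)) for (ki in 0:(k - 1L)) {
      col <- col + 1L
      gpad[ki + seq_len(H), kj + seq_len(Wd), c, ] <-
        gpad[ki + seq_len(H), kj + seq_len(Wd), c, , drop = FALSE] +
        array(gP[, col], c(H, Wd, 1L, B))
      }
    gx <- gpad[ci$p + seq_len(H), ci$p + seq_len(Wd), , , drop = FALSE]
  }
  list(gx = gx, gW = gW, gb = gb)
}

pool_parts <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ri <- seq_len(H2) * 2L; ci <- seq_len(W2) * 2L
  list(a = x[ri - 1L, ci - 1L, , , drop = FALSE],
       b = x[ri, ci - 1L, , , drop = FALSE],
       c = x[ri - 1L, ci, , , drop = FALSE],
       d = x[ri, ci, , , drop = FALSE],
       ri = ri, ci = ci, H = d[1], W = d[2], C = d[3], B = d[4])
}

maxpool_fwd <- function(x) {
  pp <- pool_parts(x)
  out <- pmax(pp$a, pp$b, pp$c, pp$d)
  list(out = out, pp = pp)
}

maxpool_bwd <- function(gy, cache) {
  pp <- cache$pp; out <- cache$out
  gx <- array(0, c(pp$H, pp$W, pp$C, pp$B))
  rem <- array(TRUE, dim(out))
  put <- function(gx, part, rows, cols, mask) {
    g <- gy * mask
    gx[rows, cols, , ] <- gx[rows, cols, , , drop = FALSE] + g
    gx
  }
  m <- (pp$a == out) & rem; rem <- rem & !m
  gx <- put(gx, pp$a, pp$ri - 1L, pp$ci - 1L, m)
  m <- (pp$b == out) & rem; rem <- rem & !m
  gx <- put(gx, pp$b, pp$ri, pp$ci - 1L, m)
  m <- (pp$c == out) & rem; rem <- rem & !m
  gx <- put(gx, pp$c, pp$ri - 1L, pp$ci, m)
  m <- (pp$d == out) & rem
  gx <- put(gx, pp$d, pp$ri, pp$ci, m)
  gx
}

avgpool_fwd <- function(x) {
  pp <- pool_parts(x)
  list(out = (pp$a + pp$b + pp$c + pp$d) / 4, pp = pp)
}

avgpool_bwd <- function(gy, cache) {
  pp <- cache$pp
  gx <- array(0, c(pp$H, pp$W, pp$C, pp$B))
  g <- gy / 4
  gx[pp$ri - 1L, pp$ci - 1L, , ] <- g
  gx[pp$ri, pp$ci - 1L, , ] <- g
  gx[pp$ri - 1L, pp$ci, , ] <- g
  gx[pp$ri, pp$ci, , ] <- g
  gx
}

# He-normal initialization for one layer's weights.
he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)

# Forward through the backbone layer stack.  x: (H, W, 1, B) array.
# Returns feature matrix (feature_dim x B) plus per-layer caches.
nn_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type == "conv") {
      cf <- conv_fwd(x, ly$W, ly$b, ly$k, ly$cin, ly$cout)
      caches[[l]] <- list(P = cf$P, x_dim = dim(x))
      x <- cf$out
    } else if (ly$type == "resconv") {
      cf <- conv_fwd(x, ly$W, ly$b, ly$k, ly$cin, ly$cout)
      caches[[l]] <- list(P = cf$P, x_dim = dim(x))
      x <- cf$out + x
    } else if (ly$type == "relu") {
      x <- pmax(x, 0)
      caches[[l]] <- list(mask = x > 0)
    } else if (ly$type == "maxpool2") {
      mf <- maxpool_fwd(x)
      caches[[l]] <- mf
      x <- mf$out
    } else if (ly$type == "avgpool2") {
      af <- avgpool_fwd(x)
      caches[[l]] <- af
      x <- af$out
    } else if (ly$type == "flatten") {
      d <- dim(x)
      caches[[l]] <- list(d = d)
      x <- matrix(x, d[1] * d[2] * d[3], d[4])
    } else if (ly$type == "fc") {
      caches[[l]] <- list(x = x)
      x <- ly$W %*% x + ly$b
    } else stop("nn_forward: unknown layer type ", ly$type)
  }
  list(out = x, caches = caches)
}

# Backward through the stack; g is the gradient w.r.t. the stack output.
# Returns per-layer parameter gradients (NULL for parameterless layers).
nn_backward <- function(layers, caches, g) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]; ca <- caches[[l]]
    if (ly$type %in% c("conv", "resconv")) {
      bb <- conv_bwd(g, ca$P, ly$W, ly$k, ly$cin, ly$cout, need_gx = l > 1L)
      grads[[l]] <- list(W = bb$gW, b = bb$gb)
      if (l > 1L) g <- if (ly$type == "resconv") bb$gx + g else bb$gx
    } else if (ly$type == "relu") {
      g <- g * ca$mask
    } else if (ly$type == "maxpool2") {
      g <- maxpool_bwd(g, ca)
    } else if (ly$type == "avgpool2") {
      g <- avgpool_bwd(g, ca)
    } else if (ly$type == "flatten") {
      g <- array(g, ca$d)
    } else if (ly$type == "fc") {
      grads[[l]] <- list(W = g %*% t(ca$x), b = rowSums(g))
      if (l > 1L) g <- t(ly$W) %*% g
    }
  }
  grads
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}
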