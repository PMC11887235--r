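#' Feature matrix
#'
#' N rows of D-dimensional features with per-row source identifiers.
#'
#' @param values N x D numeric matrix of finite values.
#' @param ids character vector of length N.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("feature_matrix: values must be finite")
  if (is.null(ids)) ids <- sprintf("x%04d", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) stop("feature_matrix: ids/nrow mismatch")
  structure(list(values = values, ids = ids), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %d x %d>\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Build the joint distribution behind the bottleneck objective
#'
#' Features become conditionals `p(y|x)` by clipping negatives to zero,
#' adding a floor of `eps = 1e-8` to every entry (an all-zero row thus
#' becomes uniform) and normalizing each row; `p(x)` is uniform and
#' `p(x, y) = p(x) p(y|x)`.
#'
#' @param F a [feature_matrix()] (or plain matrix) with `N >= 1` rows and
#'   `D >= 2` columns.
#' @return An object of class `joint_distribution` with fields `p_xy`,
#'   `p_x`, `p_y_given_x` and `ids`.
#' @export
features_to_joint <- function(F) {
  if (!inherits(F, "feature_matrix")) F <- feature_matrix(F)
  v <- F$values
  if (ncol(v) < 2L) stop("features_to_joint: need at least 2 feature columns")
  v <- pmax(v, 0) + 1e-8
  p_y_given_x <- v / rowSums(v)
  n <- nrow(v)
  structure(list(p_xy = p_y_given_x / n,
                 p_x = rep(1 / n, n),
                 p_y_given_x = p_y_given_x,
                 ids = F$ids),
            class = "joint_distribution")
}

#' Mutual information of a discrete joint distribution (nats)
#'
#' `I = sum p(a,b) log( p(a,b) / (p(a) p(b)) )` with zero-mass cells
#' contributing zero.
#'
#' @param joint nonnegative matrix summing to 1 (tolerance `1e-8`).
#' @return Nonnegative scalar in nats.
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("mutual_information: negative mass")
  if (abs(sum(joint) - 1) > 1e-8)
    stop("mutual_information: total mass must be 1")
  pa <- rowSums(joint); pb <- colSums(joint)
  idx <- joint > 0
  denom <- outer(pa, pb)
  max(0, sum(joint[idx] * log(joint[idx] / denom[idx])))
}

#' Weighted Jensen-Shannon divergence (nats)
#'
#' `JS_w(p, q) = w1 KL(p || m) + w2 KL(q || m)` with `m = w1 p + w2 q`.
#' Bounded by the weight entropy `H(w)`, attained when the supports of
#' `p` and `q` are disjoint.
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1.
#' @param w positive weights `(w1, w2)` summing to 1.
#' @return Scalar in `[0, H(w)]`.
#' @export
js_divergence <- function(p, q, w = c(0.5, 0.5)) {
  if (length(p) != length(q)) stop("js_divergence: length mismatch")
  if (length(w) != 2L || any(w <= 0) || abs(sum(w) - 1) > 1e-9)
    stop("js_divergence: w must be two positive weights summing to 1")
  m <- w[1] * p + w[2] * q
  kl <- function(a) {
    idx <- a > 0
    sum(a[idx] * log(a[idx] / m[idx]))
  }
  w[1] * kl(p) + w[2] * kl(q)
}

#' Sequential information bottleneck configuration
#'
#' @param k number of clusters, `>= 2`; the staging default is 4.
#' @param lam Lagrange multiplier balancing information preservation
#'   `I(T;Y)` against compression `I(T;X)`; the staging default is 100,
#'   which makes the compression term a `<= 1%` correction.
#' @param max_passes cap on draw-and-merge passes per restart.
#' @param restarts independent seeded restarts; the best objective wins.
#' @param seed RNG seed for initial partitions and draw orders.
#' @param tol numerical tolerance for cost ties.
#' @return An object of class `sib_config`.
#' @export
sib_config <- function(k = 4L, lam = 100, max_passes = 50L, restarts = 5L,
                       seed = 0L, tol = 1e-12) {
  k <- as.integer(k)
  if (k < 2L) stop("sib_config: k must be >= 2")
  if (lam <= 0) stop("sib_config: lam must be > 0")
  structure(list(k = k, lam = lam, max_passes = as.integer(max_passes),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 tol = tol),
            class = "sib_config")
}

# Build a cluster_state from an assignment vector (1..k, NA = drawn).
cluster_state_from_assignment <- function(assignment, joint, k, lam) {
  n <- length(assignment)
  p_t <- numeric(k)
  D <- ncol(joint$p_y_given_x)
  p_y_given_t <- matrix(0, k, D)
  for (t in seq_len(k)) {
    mem <- which(!is.na(assignment) & assignment == t)
    p_t[t] <- sum(joint$p_x[mem])
    if (length(mem) > 0)
      p_y_given_t[t, ] <- colSums(joint$p_xy[mem, , drop = FALSE]) / p_t[t]
  }
  st <- structure(list(assignment = assignment, p_t = p_t,
                       p_y_given_t = p_y_given_t, k = k, lam = lam,
                       objective = NA_real_),
                  class = "cluster_state")
  st$objective <- sib_objective(st, joint)
  st
}

#' Bottleneck objective of a cluster state, recomputed from scratch
#'
#' `L = I(T;Y) - I(T;X) / lam`.  With uniform `p(x)` and hard
#' assignments, `I(T;X)` reduces to the cluster-mass entropy `H(T)`.
#' A drawn point (`NA` assignment) counts as its own singleton cluster,
#' matching the draw-and-merge picture in which drawing temporarily
#' raises the cluster count.
#'
#' @param state a `cluster_state`.
#' @param joint the [features_to_joint()] output the state refers to.
#' @return Scalar objective value in nats.
#' @export
sib_objective <- function(state, joint) {
  a <- state$assignment
  drawn <- which(is.na(a))
  p_ty <- matrix(0, state$k + length(drawn), ncol(joint$p_xy))
  for (t in seq_len(state$k)) {
    mem <- which(!is.na(a) & a == t)
    if (length(mem)) p_ty[t, ] <- colSums(joint$p_xy[mem, , drop = FALSE])
  }
  if (length(drawn))
    p_ty[state$k + seq_along(drawn), ] <- joint$p_xy[drawn, , drop = FALSE]
  i_ty <- mutual_information(p_ty)
  p_t <- rowSums(p_ty)
  h_t <- -sum(p_t[p_t > 0] * log(p_t[p_t > 0]))
  i_ty - h_t / state$lam
}

# Merger costs of joining drawn point x to every cluster, vectorized over
# clusters.  Returns the vector Delta L(t) = Delta I2(t) - Delta I1(t)/lam,
# the *decrease* in objective caused by the merge; argmin is the best
# target.  Empty clusters cost 0 (merging a singleton "with itself").
merger_cost_vec <- function(p_t, p_y_given_t, px, pyx, lam) {
  k <- length(p_t)
  p_merged <- px + p_t
  w1 <- px / p_merged; w2 <- p_t / p_merged
  M <- w1 * matrix(pyx, k, length(pyx), byrow = TRUE) + w2 * p_y_given_t
  t1 <- log(pyx / t(M))                # D x k ; pyx > 0 by the eps floor
  kl_p <- colSums(pyx * t1)
  Q <- p_y_given_t
  r <- Q / M
  lr <- ifelse(Q > 0, log(pmax(r, .Machine$double.xmin)), 0)
  kl_q <- rowSums(Q * lr)
  js <- w1 * kl_p + w2 * kl_q
  # membership indicators over X have disjoint support, so their JS is H(w)
  hw <- -(w1 * log(w1) + w2 * ifelse(w2 > 0, log(w2), 0))
  cost <- p_merged * js - (p_merged * hw) / lam
  cost[p_t == 0] <- 0
  cost
}

#' Merger cost of re-merging a drawn point into a cluster
#'
#' The drop in the objective `L = I(T;Y) - I(T;X)/lam` caused by merging
#' the singleton `{x}` into `target_cluster`:
#' `Delta L = p_merged * JS_w[p(y|x), p(y|t)] - p_merged * H(w) / lam`
#' with `p_merged = p(x) + p(t)` and `w = (p(x), p(t)) / p_merged`.  The
#' compression term uses the membership-indicator conditionals over X,
#' whose disjoint supports reduce the JS to the weight entropy `H(w)`.
#' By construction this equals the from-scratch objective difference
#' `L(before merge) - L(after merge)` to machine precision.
#'
#' @param state a `cluster_state` in which `x_index` is drawn
#'   (`assignment[x_index]` is `NA`).
#' @param joint the corresponding [features_to_joint()] output.
#' @param x_index index of the drawn point.
#' @param target_cluster cluster index in `1..k`.
#' @param lam Lagrange multiplier; defaults to the state's.
#' @return Scalar merger cost (objective decrease; can be slightly
#'   negative through the compression term).
#' @export
merger_cost <- function(state, joint, x_index, target_cluster,
                        lam = state$lam) {
  stopifnot(inherits(state, "cluster_state"))
  if (x_index < 1L || x_index > length(state$assignment))
    stop("merger_cost: x_index out of range")
  if (!is.na(state$assignment[x_index]))
    stop("merger_cost: x_index must be drawn (assignment NA)")
  if (target_cluster < 1L || target_cluster > state$k)
    stop("merger_cost: target_cluster out of range")
  costs <- merger_cost_vec(state$p_t, state$p_y_given_t,
                           joint$p_x[x_index], joint$p_y_given_x[x_index, ],
                           lam)
  costs[target_cluster]
}

#' Sequential information-bottleneck clustering (draw-and-merge)
#'
#' Starts each restart from a seeded random balanced partition into `k`
#' clusters, then repeatedly draws each point (in a reshuffled random
#' order per pass) as a singleton cluster and re-merges it into the
#' cluster of minimal merger cost; ties go to the lowest cluster index,
#' and the sole member of a cluster is never drawn, so exactly `k`
#' non-empty clusters survive.  A restart converges when a full pass
#' reassigns nothing; the restart with the highest objective is
#' returned.  The objective trace is non-decreasing within a restart.
#'
#' @param F a [feature_matrix()] (or plain matrix) with at least `k` rows.
#' @param cfg a [sib_config()].
#' @return A `cluster_state` with fields `assignment` (1..k),
#'   `p_t`, `p_y_given_t`, `objective`, `k`, `lam`, plus `trace` (the
#'   per-merge objective sequence of the winning restart), `passes`
#'   and `converged`.
#' @export
sib_cluster <- function(F, cfg = sib_config()) {
  if (!inherits(F, "feature_matrix")) F <- feature_matrix(F)
  joint <- features_to_joint(F)
  n <- nrow(F$values)
  if (n < cfg$k) stop("sib_cluster: need at least k points")
  best <- NULL
  for (rs in seq_len(cfg$restarts)) {
    st <- withr::with_seed((cfg$seed + 7919L * (rs - 1L)) %% 2147483647L, {
      run_sib_restart(joint, cfg)
    })
    if (is.null(best) || st$objective > best$objective) best <- st
  }
  best$ids <- F$ids
  best
}

run_sib_restart <- function(joint, cfg) {
  n <- length(joint$p_x); k <- cfg$k; lam <- cfg$lam
  assignment <- sample(rep_len(seq_len(k), n))   # balanced random init
  st <- cluster_state_from_assignment(assignment, joint, k, lam)
  p_t <- st$p_t; pyt <- st$p_y_given_t
  L <- st$objective
  trace <- L
  converged <- FALSE
  pass <- 0L
  counts <- tabulate(assignment, k)
  while (pass < cfg$max_passes) {
    pass <- pass + 1L
    moved <- 0L
    for (i in sample.int(n)) {
      t_old <- assignment[i]
      if (counts[t_old] <= 1L) next           # never empty a cluster
      px <- joint$p_x[i]; pyx <- joint$p_y_given_x[i, ]
      # remove i from its cluster
      new_mass <- p_t[t_old] - px
      pyt[t_old, ] <- (p_t[t_old] * pyt[t_old, ] - px * pyx) / new_mass
      p_t[t_old] <- new_mass
      counts[t_old] <- counts[t_old] - 1L
      costs <- merger_cost_vec(p_t, pyt, px, pyx, lam)
      t_new <- which.min(costs)               # which.min: lowest index wins ties
      if (costs[t_old] - costs[t_new] <= cfg$tol) t_new <- t_old
      # merge into t_new
      merged_mass <- p_t[t_new] + px
      pyt[t_new, ] <- (p_t[t_new] * pyt[t_new, ] + px * pyx) / merged_mass
      p_t[t_new] <- merged_mass
      counts[t_new] <- counts[t_new] + 1L
      if (t_new != t_old) {
        assignment[i] <- t_new
        moved <- moved + 1L
        L <- L + costs[t_old] - costs[t_new]
        trace <- c(trace, L)
      }
    }
    if (moved == 0L) { converged <- TRUE; break }
  }
  st <- cluster_state_from_assignment(assignment, joint, k, lam)
  st$trace <- trace
  st$passes <- pass
  st$converged <- converged
  st
}

#' @export
print.cluster_state <- function(x, ...) {
  cat(sprintf("<cluster_state k=%d n=%d objective=%.6f sizes=%s>\n",
              x$k, length(x$assignment), x$objective,
              paste(tabulate(x$assignment, x$k), collapse = "/")))
  invisible(x)
}

#' Normalized mutual information between two labelings
#'
#' `NMI = 2 I(A;B) / (H(A) + H(B))`; symmetric, invariant to label
#' permutations, 1 for identical partitions and approximately 0 for
#' independent ones.  If both partitions are trivial (a single block),
#' the value is 1 when they are identical partitions and 0 otherwise.
#'
#' @param labels_a,labels_b equal-length vectors of cluster labels.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("nmi: length mismatch")
  tab <- table(labels_a, labels_b)
  p <- tab / sum(tab)
  i_ab <- mutual_information(unclass(matrix(p, nrow(p), ncol(p))))
  ent <- function(m) { q <- m[m > 0]; -sum(q * log(q)) }
  ha <- ent(rowSums(p)); hb <- ent(colSums(p))
  if (ha + hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  min(1, 2 * i_ab / (ha + hb))
}

#' k-means baseline clustering
#'
#' Thin wrapper over [stats::kmeans()] on the raw feature rows; the
#' ablation axis that replaces the draw-and-merge mechanism.
#'
#' @param F a [feature_matrix()] or matrix.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart random restarts.
#' @return List with `assignment` (1..k) and `ids`.
#' @export
kmeans_baseline <- function(F, k = 4L, seed = 0L, nstart = 10L) {
  if (!inherits(F, "feature_matrix")) F <- feature_matrix(F)
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(F$values, centers = k, nstart = nstart))
  list(assignment = as.integer(km$cluster), ids = F$ids)
}
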