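# Spike time tiling coefficient, STTC matrices, agglomerative clustering
# with optimal leaf ordering, and eigendecomposition gradients.

# fraction of [0, duration] covered by the union of +/-dt windows around
# sorted spike times
tiling_fraction <- function(times, dt, duration) {
  n <- length(times)
  if (n == 0) return(0)
  if (n == 1) {
    return((min(times + dt, duration) - max(times - dt, 0)) / duration)
  }
  gaps <- diff(times)
  inner <- sum(pmin(gaps, 2 * dt))
  first <- times[1] - max(times[1] - dt, 0)
  last <- min(times[n] + dt, duration) - times[n]
  (inner + first + last) / duration
}

# fraction of spikes in `a` that have a spike of `b` within +/-dt
tiled_proportion <- function(a, b, dt) {
  if (length(a) == 0) return(0)
  if (length(b) == 0) return(0)
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(b))
  near <- pmin(abs(a - b[lo]), abs(a - b[hi]))
  mean(near <= dt)
}

#' Spike time tiling coefficient
#'
#' Firing-rate-robust association between two spike trains:
#' \deqn{STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
#'   \frac{P_B - T_A}{1 - P_B T_A}\right)}
#' where \eqn{T_A} is the proportion of the recording covered by the union
#' of the \eqn{\pm\Delta t} tiling windows around A's spikes (merged where
#' overlapping, clipped to the recording), and \eqn{P_A} is the proportion
#' of A's spikes with a B spike inside their tiling window.
#'
#' An empty train returns 0 (flagged via attribute `empty`); a term with a
#' zero denominator (\eqn{P T = 1}) contributes 0.
#'
#' @param a,b Sorted spike time vectors (seconds).
#' @param dt_ms Tiling half-window in ms (default 20; the value is not part
#'   of the measure's definition and is reported alongside all outputs).
#' @param duration Recording duration in seconds.
#' @return STTC in `[-1, 1]`.
#' @examples
#' sttc(c(1, 2, 3), c(1, 2, 3), dt_ms = 20, duration = 10)  # 1
#' @export
sttc <- function(a, b, dt_ms = 20, duration) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    out <- 0
    attr(out, "empty") <- TRUE
    return(out)
  }
  dt <- dt_ms / 1000
  TA <- tiling_fraction(a, dt, duration)
  TB <- tiling_fraction(b, dt, duration)
  PA <- tiled_proportion(a, b, dt)
  PB <- tiled_proportion(b, a, dt)
  term <- function(P, T) {
    den <- 1 - P * T
    if (abs(den) < .Machine$double.eps) 0 else (P - T) / den
  }
  0.5 * (term(PA, TB) + term(PB, TA))
}

#' STTC matrix of a spike train set
#'
#' Symmetric unit-by-unit STTC matrix; the diagonal is 1 by convention.
#'
#' @param spikes A [spike_train_set()].
#' @param dt_ms Tiling half-window in ms (default 20).
#' @return Object of class `sttc_matrix`: list with `values` (symmetric
#'   matrix with unit-id dimnames), `dt_ms`, `duration`.
#' @export
sttc_matrix <- function(spikes, dt_ms = 20) {
  stopifnot(inherits(spikes, "spike_train_set"))
  tr <- spike_list(spikes)
  ids <- names(tr)
  n <- length(tr)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- as.numeric(sttc(tr[[i]], tr[[j]], dt_ms,
                                            spikes$duration))
    }
  }
  dimnames(m) <- list(ids, ids)
  structure(list(values = m, dt_ms = dt_ms, duration = spikes$duration),
            class = "sttc_matrix")
}

#' @export
print.sttc_matrix <- function(x, ...) {
  cat(sprintf("<sttc_matrix> %d units, dt = %g ms\n", nrow(x$values), x$dt_ms))
  invisible(x)
}

#' @rdname sttc_matrix
#' @param x An `sttc_matrix`.
#' @param ... Unused.
#' @export
tidy.sttc_matrix <- function(x, ...) {
  ids <- rownames(x$values)
  n <- length(ids)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(unit_i = ids[idx[, 1]], unit_j = ids[idx[, 2]],
         sttc = x$values[idx])
}

# ---- optimal leaf ordering --------------------------------------------------

# Bar-Joseph optimal leaf ordering: reorder an hclust tree's leaves, without
# changing its topology, to minimise the sum of adjacent-leaf distances.
# Returns the leaf order (indices into the original observations).
optimal_leaf_order <- function(hc, d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  # node -> per (left extreme, right extreme) best internal cost + backtrack
  solve_node <- function(node) {
    if (node < 0) {
      leaf <- -node
      return(list(leaves = leaf,
                  cost = matrix(0, 1, 1, dimnames = list(leaf, leaf)),
                  kind = "leaf"))
    }
    L <- solve_node(hc$merge[node, 1])
    R <- solve_node(hc$merge[node, 2])
    A <- L$leaves
    B <- R$leaves
    leaves <- c(A, B)
    nl <- length(A)
    nr <- length(B)
    cost <- matrix(Inf, length(leaves), length(leaves),
                   dimnames = list(leaves, leaves))
    pick <- array(NA_integer_, dim = c(length(leaves), length(leaves), 2),
                  dimnames = list(leaves, leaves, NULL))
    cA <- as.character(A)
    cB <- as.character(B)
    # orientation: left block from one child, right block from the other
    fill <- function(Xl, Xr, cl, cr) {
      for (u in rownames(cl)) {
        for (w in colnames(cr)) {
          # bridge = min over m in Xl-block, k in Xr-block
          bridge <- outer(cl[u, , drop = TRUE], cr[, w, drop = TRUE], "+") +
            dm[as.integer(colnames(cl)), as.integer(rownames(cr)), drop = FALSE]
          best <- arrayInd(which.min(bridge), dim(bridge))
          cost[u, w] <<- bridge[best]
          pick[u, w, ] <<- c(as.integer(colnames(cl)[best[1]]),
                             as.integer(rownames(cr)[best[2]]))
        }
      }
    }
    fill(A, B, L$cost, R$cost)
    fill(B, A, R$cost, L$cost)
    list(leaves = leaves, cost = cost, pick = pick,
         left = L, right = R, kind = "internal")
  }
  order_node <- function(sol, u, w) {
    if (sol$kind == "leaf") return(sol$leaves)
    mk <- sol$pick[as.character(u), as.character(w), ]
    m <- mk[1]
    k <- mk[2]
    if (u %in% sol$left$leaves) {
      c(order_node(sol$left, u, m), order_node(sol$right, k, w))
    } else {
      c(order_node(sol$right, u, m), order_node(sol$left, k, w))
    }
  }
  root <- solve_node(nrow(hc$merge))
  best <- arrayInd(which.min(root$cost), dim(root$cost))
  u <- as.integer(rownames(root$cost)[best[1]])
  w <- as.integer(colnames(root$cost)[best[2]])
  order_node(root, u, w)
}

#' Agglomerative clustering of an STTC matrix
#'
#' Caps the off-diagonal STTC values (agglomerative clustering is sensitive
#' to outliers), computes Euclidean distances between matrix rows, builds an
#' agglomerative tree, reorders its leaves to the optimal arrangement
#' (minimum total adjacent-leaf distance for the fixed topology), and cuts
#' into `k` clusters.
#'
#' @param m An [sttc_matrix()].
#' @param cap Off-diagonal cap (default 0.3, around the 98th percentile of
#'   typical slice data). Use `cap_quantile` instead for percentile capping.
#' @param k Number of clusters (default 2).
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @param cap_quantile Optional off-diagonal quantile to cap at, overriding
#'   `cap`.
#' @return Tibble `unit_id`, `cluster` with attributes `leaf_order`
#'   (unit ids in optimal dendrogram order), `hclust`, and `degenerate`
#'   (`TRUE` when all off-diagonal values are equal and any partition is as
#'   good as any other).
#' @export
hierarchical_clusters <- function(m, cap = 0.3, k = 2, linkage = "average",
                                  cap_quantile = NULL) {
  stopifnot(inherits(m, "sttc_matrix"))
  v <- m$values
  if (k > nrow(v)) abort("More clusters than units.")
  off <- v[upper.tri(v)]
  if (!is.null(cap_quantile)) cap <- as.numeric(quantile(off, cap_quantile))
  capped <- pmin(v, cap)
  diag(capped) <- diag(v)
  degenerate <- length(unique(round(off, 12))) <= 1
  d <- dist(capped)
  hc <- hclust(d, method = linkage)
  ord <- optimal_leaf_order(hc, d)
  labels <- cutree(hc, k = k)
  out <- tibble(unit_id = rownames(v), cluster = as.integer(labels))
  attr(out, "leaf_order") <- rownames(v)[ord]
  attr(out, "hclust") <- hc
  attr(out, "degenerate") <- degenerate
  if (degenerate) warn("All off-diagonal STTC values equal; clustering is arbitrary.")
  out
}

#' Eigendecomposition gradient of an STTC matrix
#'
#' The STTC matrix is positive semidefinite (like a correlation matrix), so
#' its eigendecomposition has a PCA-like reading. Each unit is scored by the
#' top eigenvectors; on recordings with two reciprocally active populations
#' the block-separating eigenvector forms a spatial gradient along the cell
#' layer.
#'
#' @param m An [sttc_matrix()] (or any symmetric matrix).
#' @param n_vectors Number of top eigenvectors to report (default 2; which
#'   of the top two separates the blocks depends on whether the leading one
#'   is a near-constant Perron vector).
#' @return Object of class `eigen_gradient`: list with `eigenvalues`
#'   (descending) and `scores` (tibble `unit_id`, `ev1`, `ev2`, ...). Each
#'   eigenvector is sign-fixed so its largest-magnitude entry is positive.
#'   Attribute `degenerate` flags a (near-)identity spectrum.
#' @export
eigen_gradient <- function(m, n_vectors = 2) {
  v <- if (inherits(m, "sttc_matrix")) m$values else m
  if (!isSymmetric(unname(v), tol = 1e-8)) abort("Matrix must be symmetric.")
  e <- eigen(v, symmetric = TRUE)
  k <- min(n_vectors, ncol(v))
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(vecs[, i]))
    if (vecs[j, i] < 0) vecs[, i] <- -vecs[, i]
  }
  ids <- rownames(v) %||% as.character(seq_len(nrow(v)))
  scores <- as_tibble(setNames(as.data.frame(vecs), paste0("ev", seq_len(k))))
  scores <- dplyr::bind_cols(tibble(unit_id = ids), scores)
  degenerate <- diff(range(e$values)) < 1e-10
  structure(list(eigenvalues = e$values, scores = scores),
            class = "eigen_gradient", degenerate = degenerate)
}

#' @export
print.eigen_gradient <- function(x, ...) {
  cat(sprintf("<eigen_gradient> top eigenvalues: %s\n",
              paste(signif(head(x$eigenvalues, 4), 4), collapse = ", ")))
  invisible(x)
}
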